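#' Concentric multilayer sphere model (analytic oracle)
#'
#' Semi-analytic forward model: a current dipole inside an N-shell
#' concentric spherical conductor (air outside), solved by a Legendre series
#' with per-degree radial transfer systems.  Serves as the independent
#' oracle for the BEM solver; the dipole may sit in any conducting region,
#' including the shell regions between interfaces.
#'
#' @param radii strictly decreasing interface radii in meters (outermost
#'   first).
#' @param sigmas conductivities (S/m) of the regions bounded by each
#'   interface, outermost region first (region i lies between `radii[i]` and
#'   `radii[i+1]`; the last value is the innermost ball).
#' @param n_terms series truncation degree (default 200).
#' @return an object of class `sphere_model`.
#' @export
sphere_model <- function(radii, sigmas, n_terms = 200L) {
  radii <- as.numeric(radii); sigmas <- as.numeric(sigmas)
  if (any(diff(radii) >= 0)) stop("radii must be strictly decreasing")
  if (length(sigmas) != length(radii)) stop("one conductivity per region/interface")
  if (any(sigmas <= 0)) stop("all conductivities must be > 0")
  if (n_terms < 1L) stop("n_terms must be >= 1")
  structure(list(radii = radii, sigmas = sigmas, n_terms = as.integer(n_terms)),
            class = "sphere_model")
}

# Region index containing radius b: 1..N (region i between R_i and R_{i+1},
# region N the innermost ball); 0 if outside.
sphere_region <- function(model, b) {
  R <- model$radii
  if (b >= R[1]) return(0L)
  for (i in seq_along(R)) if (b >= c(R, 0)[i + 1L]) return(i)
  length(R)
}

#' Surface potential of a dipole in a multilayer sphere
#'
#' Computes the electric potential on (or outside regions of) the outer
#' sphere surface for a current dipole at arbitrary position and moment.
#' The dipole is decomposed into radial (Legendre `P_n`) and tangential
#' (`P_n^1 cos phi`) parts in a frame aligned with its position vector; for
#' each degree n a small linear system couples the per-region expansion
#' coefficients (scaled radial powers, no overflow up to high degree).
#'
#' @param model a `sphere_model`.
#' @param dip a `dipole` (its `sigma_local` is ignored; the region
#'   conductivity is used).
#' @param points N x 3 evaluation points on the outer surface (meters).
#' @return numeric vector of potentials (V).
#' @export
sphere_potential <- function(model, dip, points) {
  points <- rbind_points(points)
  R <- model$radii
  sig <- model$sigmas
  N <- length(R)
  p0 <- dip$position
  b <- sqrt(sum(p0^2))
  s_reg <- sphere_region(model, b)
  if (s_reg == 0L) stop("dipole outside the outermost sphere")
  # eccentricity relative to the nearest enclosing interface governs the
  # series convergence rate
  ecc <- b / R[s_reg]
  if (ecc >= 0.95 && model$n_terms < 400L)
    stop("dipole eccentricity >= 0.95 requires larger n_terms for series accuracy")
  sigma_s <- sig[s_reg]

  # dipole-aligned frame: zh along the position (radial); for a central
  # dipole align zh with the moment instead
  if (b > 1e-12) {
    zh <- p0 / b
  } else {
    zh <- dip$moment / sqrt(sum(dip$moment^2))
  }
  q_r <- sum(dip$moment * zh)
  qt <- dip$moment - q_r * zh
  qtn <- sqrt(sum(qt^2))
  if (qtn > 1e-300) {
    xh <- qt / qtn
  } else {
    # any unit vector orthogonal to zh
    seed <- if (abs(zh[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    xh <- seed - sum(seed * zh) * zh
    xh <- xh / sqrt(sum(xh^2))
  }
  yh <- c(zh[2] * xh[3] - zh[3] * xh[2],
          zh[3] * xh[1] - zh[1] * xh[3],
          zh[1] * xh[2] - zh[2] * xh[1])
  # observation angles
  rr <- sqrt(rowSums(points^2))
  ct <- as.numeric(points %*% zh) / rr
  ct <- pmin(1, pmax(-1, ct))
  st <- sqrt(pmax(0, 1 - ct^2))
  cphi <- ifelse(st > 1e-14,
                 as.numeric(points %*% xh) / (rr * st), 0)

  nmax <- model$n_terms
  # radial secondary coefficients per degree, evaluated at the outer surface
  coefs <- sphere_series_coefs(R, sig, s_reg, b, sigma_s, nmax)
  # Legendre recurrences accumulated on the fly
  Pnm1 <- rep(1, length(ct))   # P_0
  Pn <- ct                     # P_1
  # P_n^1 (positive convention: sin(theta) * dP_n/dx)
  P1nm1 <- rep(0, length(ct))  # P_0^1
  P1n <- st                    # P_1^1
  phi_r <- numeric(length(ct))
  phi_t <- numeric(length(ct))
  tail_mag <- Inf
  partial <- 0
  for (n in seq_len(nmax)) {
    term_r <- coefs$rad[n] * Pn
    term_t <- coefs$tan[n] * P1n * cphi
    phi_r <- phi_r + term_r
    phi_t <- phi_t + term_t
    tail_mag <- max(abs(coefs$rad[n]), abs(coefs$tan[n]))
    partial <- max(partial, max(abs(phi_r)), max(abs(phi_t)))
    if (n >= 10L && tail_mag < 1e-10 * max(partial, 1e-300)) break
    # advance recurrences to degree n+1
    Pnp1 <- ((2 * n + 1) * ct * Pn - n * Pnm1) / (n + 1)
    P1np1 <- ((2 * n + 1) * ct * P1n - (n + 1) * P1nm1) / n
    Pnm1 <- Pn; Pn <- Pnp1
    P1nm1 <- P1n; P1n <- P1np1
  }
  q_r * phi_r + qtn * phi_t
}

# Per-degree radial solves.  Secondary potential in region k:
#   u_k(r) = a_k (r/R_k)^n + b_k (Rin_k / r)^(n+1),  Rin_k = inner radius
# (innermost region has only the a_N term).  The primary (infinite-medium)
# potential of the dipole lives in the source region s:
#   radial moment:    r > b: n (b/r)^(n-1) / (4 pi sigma r^2) P_n
#                     r < b: -(n+1) (r/b)^n / (4 pi sigma b^2) P_n
#   tangential:       r > b: (b/r)^(n-1) / (4 pi sigma r^2) P_n^1 cos(phi)
#                     r < b: (r/b)^n / (4 pi sigma b^2) P_n^1 cos(phi)
# Interface conditions: potential continuous; sigma * d/dr continuous
# (0 against air at the outer surface).  Returns the total potential
# evaluated at the outer radius per degree, separately for unit radial and
# unit tangential moments.
sphere_series_coefs <- function(R, sig, s_reg, b, sigma_s, nmax) {
  N <- length(R)
  Rin <- c(R[-1], 0)          # inner radius of each region (0 for the ball)
  nunk <- 2L * N - 1L
  rad <- numeric(nmax)
  tan_ <- numeric(nmax)
  # unknown layout: a_1, b_1, a_2, b_2, ..., a_{N-1}, b_{N-1}, a_N
  ai <- function(k) 2L * k - 1L
  bi <- function(k) 2L * k
  for (n in seq_len(nmax)) {
    for (comp in 1:2) {  # 1 = radial, 2 = tangential
      A <- matrix(0, nunk, nunk)
      rhs <- numeric(nunk)
      row <- 0L
      for (i in seq_len(N)) {   # interface i at radius R[i]
        up <- i - 1L            # region above (0 = air)
        lo <- i                 # region below
        # value and sigma*derivative of basis functions at R[i]
        # region k basis: (r/R_k)^n and (Rin_k/r)^(n+1)
        val_a <- function(k) (R[i] / R[k])^n
        val_b <- function(k) (Rin[k] / R[i])^(n + 1)
        der_a <- function(k) n / R[i] * (R[i] / R[k])^n
        der_b <- function(k) -(n + 1) / R[i] * (Rin[k] / R[i])^(n + 1)
        # primary potential value/derivative at R[i] for the source region
        prim <- primary_terms(n, comp, b, sigma_s, R[i])
        if (up == 0L) {
          # air: sigma_lo * d(total)/dr = 0
          row <- row + 1L
          A[row, ai(lo)] <- der_a(lo)
          if (lo < N) A[row, bi(lo)] <- der_b(lo)
          if (lo == s_reg) rhs[row] <- -prim$der
        } else {
          # continuity of potential
          row <- row + 1L
          A[row, ai(up)] <- val_a(up)
          if (up < N) A[row, bi(up)] <- val_b(up)
          A[row, ai(lo)] <- A[row, ai(lo)] - val_a(lo)
          if (lo < N) A[row, bi(lo)] <- A[row, bi(lo)] - val_b(lo)
          if (up == s_reg) rhs[row] <- rhs[row] - prim$val
          if (lo == s_reg) rhs[row] <- rhs[row] + prim$val
          # continuity of sigma * d/dr
          row <- row + 1L
          A[row, ai(up)] <- sig[up] * der_a(up)
          if (up < N) A[row, bi(up)] <- sig[up] * der_b(up)
          A[row, ai(lo)] <- A[row, ai(lo)] - sig[lo] * der_a(lo)
          if (lo < N) A[row, bi(lo)] <- A[row, bi(lo)] - sig[lo] * der_b(lo)
          if (up == s_reg) rhs[row] <- rhs[row] - sig[up] * prim$der
          if (lo == s_reg) rhs[row] <- rhs[row] + sig[lo] * prim$der
        }
      }
      sol <- tryCatch(solve(A, rhs), error = function(e) rep(0, nunk))
      # total potential at the outer surface: secondary of region 1 + primary
      # if the source region is region 1
      tot <- sol[ai(1L)] * 1 + if (N > 1L) sol[bi(1L)] * (Rin[1] / R[1])^(n + 1) else 0
      if (s_reg == 1L) tot <- tot + primary_terms(n, comp, b, sigma_s, R[1])$val
      if (comp == 1L) rad[n] <- tot else tan_[n] <- tot
    }
  }
  list(rad = rad, tan = tan_)
}

# primary potential radial factors (per degree n) at radius r, for unit
# radial (comp 1, multiplies P_n) and unit tangential (comp 2, multiplies
# P_n^1 cos phi) dipole moments at radius b in an infinite medium sigma
primary_terms <- function(n, comp, b, sigma, r) {
  c4 <- 4 * pi * sigma
  if (r >= b) {
    ratio <- if (b == 0) { if (n == 1L) 1 else 0 } else (b / r)^(n - 1)
    if (comp == 1L) {
      val <- n * ratio / (c4 * r^2)
      der <- -n * (n + 1) * ratio / (c4 * r^3)
    } else {
      val <- ratio / (c4 * r^2)
      der <- -(n + 1) * ratio / (c4 * r^3)
    }
  } else {
    ratio <- (r / b)^n
    if (comp == 1L) {
      val <- -(n + 1) * ratio / (c4 * b^2)
      der <- -(n + 1) * n * ratio / (c4 * b^2 * r)
    } else {
      val <- ratio / (c4 * b^2)
      der <- n * ratio / (c4 * b^2 * r)
    }
  }
  list(val = val, der = der)
}

#' RDM and MAG forward-error metrics
#'
#' Relative difference measure (shape error)
#' `RDM = || V_test/||V_test|| - V_ref/||V_ref|| ||_2` (range 0..2) and
#' magnitude ratio `MAG = ||V_test|| / ||V_ref||`.
#'
#' @param V_ref reference potentials (nonzero vector).
#' @param V_test test potentials (same length).
#' @return named list with `rdm` and `mag`.
#' @export
rdm_mag <- function(V_ref, V_test) {
  V_ref <- as.numeric(V_ref); V_test <- as.numeric(V_test)
  if (length(V_ref) != length(V_test)) stop("length mismatch")
  nr <- sqrt(sum(V_ref^2))
  nt <- sqrt(sum(V_test^2))
  if (nr == 0) stop("reference vector has zero norm")
  list(rdm = sqrt(sum((V_test / nt - V_ref / nr)^2)), mag = nt / nr)
}
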