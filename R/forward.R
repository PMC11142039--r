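#' Current dipole source
#'
#' @param position length-3 position (meters).
#' @param moment length-3 dipole moment (A m), nonzero.
#' @param sigma_local conductivity (S/m) of the compartment containing the
#'   dipole; if `NA` it is resolved from the head model at solve time.
#' @return an object of class `dipole`.
#' @export
dipole <- function(position, moment, sigma_local = NA_real_) {
  position <- as.numeric(position); moment <- as.numeric(moment)
  stopifnot(length(position) == 3L, length(moment) == 3L)
  if (sum(moment^2) == 0) stop("dipole moment must be nonzero")
  structure(list(position = position, moment = moment,
                 sigma_local = sigma_local), class = "dipole")
}

#' @export
print.dipole <- function(x, ...) {
  cat(sprintf("dipole at (%.1f, %.1f, %.1f) mm, |q| = %.3g nA m, sigma = %.4g S/m\n",
              x$position[1] * 1e3, x$position[2] * 1e3, x$position[3] * 1e3,
              sqrt(sum(x$moment^2)) * 1e9, x$sigma_local))
  invisible(x)
}

#' Uniform impressed-field source
#'
#' An externally imposed uniform electric field `E0` (V/m), used for the
#' classical sphere-in-uniform-field benchmark.
#' @param E0 length-3 field vector (V/m).
#' @return an object of class `uniform_field`.
#' @export
uniform_field <- function(E0) {
  E0 <- as.numeric(E0)
  stopifnot(length(E0) == 3L)
  structure(list(E0 = E0), class = "uniform_field")
}

#' Impressed (primary) electric field of a source
#'
#' For a current dipole the infinite-homogeneous-medium field
#' `E^i = -grad phi^i`, `phi^i(r) = q.(r-p) / (4 pi sigma |r-p|^3)`; for a
#' uniform-field source the constant `E0`.
#'
#' @param source a `dipole` or `uniform_field`.
#' @param points N x 3 evaluation points (meters).
#' @return N x 3 matrix of field vectors (V/m).
#' @export
impressed_field <- function(source, points) {
  points <- rbind_points(points)
  if (inherits(source, "uniform_field"))
    return(matrix(source$E0, nrow(points), 3, byrow = TRUE))
  stopifnot(inherits(source, "dipole"))
  sig <- source$sigma_local
  if (is.na(sig)) stop("dipole sigma_local is unset; solve through a head model or set it")
  d <- sweep(points, 2, source$position)
  r2 <- rowSums(d^2)
  if (any(r2 < 1e-18))
    stop("impressed_field: evaluation point coincides with the dipole position")
  r <- sqrt(r2)
  qd <- d %*% source$moment  # q . (r - p)
  # E = [3 (q.d) d / r^2 - q] / (4 pi sigma r^3)
  (3 * as.numeric(qd) / r2 * d -
     matrix(source$moment, nrow(points), 3, byrow = TRUE)) /
    (4 * pi * sig * r^3)
}

#' Impressed (primary) potential of a source
#'
#' @param source a `dipole` or `uniform_field` (potential `-E0 . r`).
#' @param points N x 3 evaluation points (meters).
#' @return numeric vector of potentials (V).
#' @export
impressed_potential <- function(source, points) {
  points <- rbind_points(points)
  if (inherits(source, "uniform_field"))
    return(-as.numeric(points %*% source$E0))
  sig <- source$sigma_local
  if (is.na(sig)) stop("dipole sigma_local is unset")
  d <- sweep(points, 2, source$position)
  r2 <- rowSums(d^2)
  if (any(r2 < 1e-18))
    stop("impressed_potential: evaluation at the dipole singularity")
  unname(as.numeric(d %*% source$moment) / (4 * pi * sig * r2^1.5))
}

# ---- flattened per-facet view of a head model --------------------------------

# Concatenates interfaces into flat facet arrays and precomputes the
# near-field sparse correction; reused across GMRES iterations and AMR steps.
forward_context <- function(model, near_factor = 3) {
  meshes <- model$interfaces
  nf <- facet_counts(model)
  off <- cumsum(c(0L, nf[-length(nf)]))
  cent <- do.call(rbind, lapply(meshes, `[[`, "centroid"))
  nrm <- do.call(rbind, lapply(meshes, `[[`, "normal"))
  area <- unlist(lapply(meshes, `[[`, "area"), use.names = FALSE)
  K <- rep(model$K, nf)
  iface <- rep(seq_along(nf), nf)
  # global vertex/face arrays (faces reindexed into the stacked vertex table)
  voff <- cumsum(c(0L, vapply(meshes, function(m) nrow(m$vertices), integer(1))))
  V <- do.call(rbind, lapply(meshes, `[[`, "vertices"))
  F <- do.call(rbind, lapply(seq_along(meshes),
                             function(i) meshes[[i]]$faces + voff[i]))
  storage.mode(F) <- "integer"
  len <- sqrt(area)
  corr <- cb_near_correction(V, F, cent, nrm, area, len, near_factor)
  Cmat <- Matrix::sparseMatrix(i = corr$i, j = corr$j, x = corr$x,
                               dims = c(nrow(cent), nrow(cent)))
  list(model = model, cent = cent, nrm = nrm, area = area, K = K,
       iface = iface, V = V, F = F, len = len, near_factor = near_factor,
       Cmat = Cmat, offsets = off, nfacets = nf)
}

# per-interface area-weighted mean removal (monopole deflation); the
# continuum charge density carries zero total charge on every closed
# interface, so removing the discrete monopole mode keeps the system
# consistent while enforcing charge neutrality exactly
deflate_monopole <- function(ctx, rho) {
  for (i in seq_along(ctx$nfacets)) {
    idx <- which(ctx$iface == i)
    a <- ctx$area[idx]
    rho[idx] <- rho[idx] - sum(rho[idx] * a) / sum(a)
  }
  rho
}

#' Discretized charge-integral operator
#'
#' Applies the collocation operator of the charge-based BEM,
#' `(A rho)_m = rho_m / 2 - K_m n_m . sum_{n != m} (rho_n A_n / 4 pi)
#' (r_m - r_n)/|r_m - r_n|^3`, with near-field analytic triangle integration
#' for facet pairs closer than `near_factor` local mesh lengths.  The n-body
#' sum is delegated to the selected backend.
#'
#' @param model a `head_model` (or a prebuilt internal context).
#' @param rho per-facet charge density values (rho/eps0 units, V/m),
#'   concatenated over interfaces outermost first.
#' @param backend `"compiled"` (C++ direct sum, default) or `"reference"`
#'   (pure-R direct sum, the independent check).
#' @param near_factor near-field radius in local mesh lengths (default 3).
#' @param deflate remove the per-interface monopole mode before and after
#'   the kernel (the solver's charge-conservation constraint); default
#'   `FALSE` for the bare operator.
#' @return per-facet result vector.
#' @export
apply_operator <- function(model, rho, backend = getOption("chargebem.backend", "compiled"),
                           near_factor = 3, deflate = FALSE) {
  ctx <- if (inherits(model, "head_model")) forward_context(model, near_factor) else model
  M <- nrow(ctx$cent)
  if (length(rho) != M) stop("rho length must equal the total facet count (", M, ")")
  if (deflate) rho <- deflate_monopole(ctx, rho)
  s <- nbody_ndot(ctx, rho, backend) + as.numeric(ctx$Cmat %*% rho)
  out <- rho / 2 - ctx$K * s
  if (deflate) out <- deflate_monopole(ctx, out)
  out
}

# n_m . E_sec sums (without near correction), switchable backend
nbody_ndot <- function(ctx, rho, backend) {
  w <- rho * ctx$area
  if (backend == "compiled") {
    cb_field_sum(ctx$cent, ctx$nrm, ctx$cent, w, seq_len(nrow(ctx$cent)))
  } else if (backend == "reference") {
    nbody_ndot_reference(ctx$cent, ctx$nrm, ctx$cent, w, exclude_self = TRUE)
  } else stop("unknown backend: ", backend)
}

# Pure-R direct sum: the reference backend of the n-body contract.
# Chunked over targets to bound memory; O(N M) time.
nbody_ndot_reference <- function(targets, normals, src, w, exclude_self = FALSE) {
  N <- nrow(targets)
  out <- numeric(N)
  chunk <- max(1L, floor(2e6 / nrow(src)))
  for (s0 in seq(1L, N, by = chunk)) {
    s1 <- min(N, s0 + chunk - 1L)
    idx <- s0:s1
    dx <- outer(targets[idx, 1], src[, 1], "-")
    dy <- outer(targets[idx, 2], src[, 2], "-")
    dz <- outer(targets[idx, 3], src[, 3], "-")
    r2 <- dx^2 + dy^2 + dz^2
    if (exclude_self) r2[cbind(seq_along(idx), idx)] <- Inf
    ir3 <- 1 / (r2 * sqrt(r2))
    ndot <- normals[idx, 1] * dx + normals[idx, 2] * dy + normals[idx, 3] * dz
    out[idx] <- as.numeric((ndot * ir3) %*% w) / (4 * pi)
  }
  out
}

# restarted GMRES (Arnoldi + Givens rotations), matrix-free
gmres_solve <- function(apply_fn, b, x0 = NULL, tol = 1e-6, restart = 200L,
                        max_outer = 5L) {
  n <- length(b)
  bnorm <- sqrt(sum(b^2))
  if (bnorm == 0) return(list(x = numeric(n), resid = 0, iters = 0L, converged = TRUE,
                              history = numeric(0)))
  x <- if (is.null(x0)) numeric(n) else x0
  iters <- 0L
  history <- numeric(0)
  for (outer in seq_len(max_outer)) {
    r <- b - apply_fn(x)
    beta <- sqrt(sum(r^2))
    history <- c(history, beta / bnorm)
    if (beta / bnorm <= tol)
      return(list(x = x, resid = beta / bnorm, iters = iters, converged = TRUE,
                  history = history))
    m <- restart
    Vk <- matrix(0, n, m + 1L)
    H <- matrix(0, m + 1L, m)
    cs <- sn <- numeric(m)
    g <- numeric(m + 1L)
    Vk[, 1] <- r / beta
    g[1] <- beta
    k_used <- 0L
    for (k in seq_len(m)) {
      w <- apply_fn(Vk[, k])
      iters <- iters + 1L
      for (j in seq_len(k)) {
        H[j, k] <- sum(w * Vk[, j])
        w <- w - H[j, k] * Vk[, j]
      }
      H[k + 1L, k] <- sqrt(sum(w^2))
      if (H[k + 1L, k] > 1e-300) Vk[, k + 1L] <- w / H[k + 1L, k]
      # apply previous Givens rotations
      for (j in seq_len(k - 1L)) {
        t1 <- cs[j] * H[j, k] + sn[j] * H[j + 1L, k]
        H[j + 1L, k] <- -sn[j] * H[j, k] + cs[j] * H[j + 1L, k]
        H[j, k] <- t1
      }
      denom <- sqrt(H[k, k]^2 + H[k + 1L, k]^2)
      cs[k] <- H[k, k] / denom
      sn[k] <- H[k + 1L, k] / denom
      H[k, k] <- denom
      H[k + 1L, k] <- 0
      g[k + 1L] <- -sn[k] * g[k]
      g[k] <- cs[k] * g[k]
      k_used <- k
      history <- c(history, abs(g[k + 1L]) / bnorm)
      if (abs(g[k + 1L]) / bnorm <= tol) break
    }
    y <- backsolve(H[seq_len(k_used), seq_len(k_used), drop = FALSE],
                   g[seq_len(k_used)])
    x <- x + Vk[, seq_len(k_used), drop = FALSE] %*% y
    x <- as.numeric(x)
    if (abs(g[k_used + 1L]) / bnorm <= tol)
      return(list(x = x, resid = abs(g[k_used + 1L]) / bnorm, iters = iters,
                  converged = TRUE, history = history))
  }
  list(x = x, resid = history[length(history)], iters = iters, converged = FALSE,
       history = history)
}

#' Solve for the induced surface charge density
#'
#' Solves the discretized charge-based BEM system for a dipole (or uniform
#' field) source in a nested-interface head model.  The solver works in
#' `rho / eps0` units (V/m), deflates the per-interface monopole mode (exact
#' charge neutrality on every closed interface), and uses either a dense LU
#' factorization (small systems) or restarted GMRES (matrix-free, default
#' for larger systems).
#'
#' @param model a `head_model`.
#' @param source a `dipole` (position strictly inside the model; its
#'   `sigma_local` is resolved from the containing compartment when unset)
#'   or a `uniform_field`.
#' @param tol relative residual tolerance in (0, 1e-2] (default 1e-6).
#' @param method `"auto"` (dense below 3000 facets), `"dense"`, or
#'   `"gmres"`.
#' @param backend n-body backend for the matrix-free path.
#' @param near_factor near-field radius in local mesh lengths.
#' @param warm_start optional initial charge vector (GMRES path).
#' @param context optional prebuilt forward context (internal reuse).
#' @return an object of class `charge_solution` with fields `rho` (per-facet
#'   charge density, rho/eps0 units), `model`, `source`, `stats`
#'   (iterations, residual), and the flattened context.
#' @export
solve_charges <- function(model, source, tol = 1e-6,
                          method = c("auto", "dense", "gmres"),
                          backend = getOption("chargebem.backend", "compiled"),
                          near_factor = 3, warm_start = NULL, context = NULL) {
  method <- match.arg(method)
  if (!(tol > 0 && tol <= 1e-2)) stop("tol must be in (0, 1e-2]")
  ctx <- context %||% forward_context(model, near_factor)
  if (inherits(source, "dipole")) {
    if (is.na(source$sigma_local)) {
      sig <- local_sigma(model, source$position)
      if (sig == 0) stop("dipole position is outside the model")
      source$sigma_local <- sig
    }
    dmin <- min(sqrt(rowSums(sweep(ctx$cent, 2, source$position)^2)))
    if (dmin < 1e-9) stop("dipole position coincides with a facet centroid")
  }
  Ei <- impressed_field(source, ctx$cent)
  b <- ctx$K * rowSums(Ei * ctx$nrm)
  b <- deflate_monopole(ctx, b)
  M <- nrow(ctx$cent)
  if (method == "auto") method <- if (M <= 3000L) "dense" else "gmres"
  if (method == "dense") {
    A <- dense_operator(ctx)
    rho <- solve_deflated_dense(ctx, A, b)
    stats <- list(iterations = NA_integer_, residual = relative_residual(ctx, rho, b, backend),
                  method = "dense")
  } else {
    apply_fn <- function(x) apply_operator(ctx, x, backend = backend, deflate = TRUE)
    x0 <- if (!is.null(warm_start)) deflate_monopole(ctx, warm_start) else NULL
    sol <- gmres_solve(apply_fn, b, x0 = x0, tol = tol)
    if (!sol$converged)
      stop(sprintf("GMRES did not converge: residual %.3g after %d iterations (history: %s)",
                   sol$resid, sol$iters,
                   paste(sprintf("%.2g", utils::tail(sol$history, 8)), collapse = ", ")))
    rho <- deflate_monopole(ctx, sol$x)
    stats <- list(iterations = sol$iters, residual = sol$resid, method = "gmres")
  }
  structure(list(rho = as.numeric(rho), model = ctx$model, source = source,
                 stats = stats, context = ctx), class = "charge_solution")
}

dense_operator <- function(ctx) {
  cb_assemble_dense(ctx$V, ctx$F, ctx$cent, ctx$nrm, ctx$area, ctx$K,
                    ctx$len, ctx$near_factor)
}

# Solve (P A P + D) x = P b where P = I - D removes the per-interface
# area-weighted mean; the D term renders the deflated matrix invertible and
# the solution satisfies D x = 0 (exact per-interface neutrality).
solve_deflated_dense <- function(ctx, A, b) {
  M <- nrow(A)
  Pmat <- diag(M)
  D <- matrix(0, M, M)
  for (i in seq_along(ctx$nfacets)) {
    idx <- which(ctx$iface == i)
    a <- ctx$area[idx]
    D[idx, idx] <- matrix(1, length(idx), 1) %*% (a / sum(a))
  }
  P <- Pmat - D
  B <- P %*% A %*% P + D
  as.numeric(solve(B, as.numeric(P %*% b)))
}

relative_residual <- function(ctx, rho, b, backend = "compiled") {
  r <- b - apply_operator(ctx, rho, backend = backend, deflate = TRUE)
  sqrt(sum(r^2)) / sqrt(sum(b^2))
}

#' @export
print.charge_solution <- function(x, ...) {
  neut <- charge_neutrality(x)
  cat(sprintf("charge_solution: %d facets, %s, residual %.2e, neutrality defect %.2e\n",
              length(x$rho), x$stats$method, x$stats$residual, neut))
  invisible(x)
}

#' Global charge-neutrality defect
#'
#' `|sum rho_m A_m| / sum |rho_m| A_m`; ~0 after every solve (the solver
#' enforces per-interface neutrality).
#' @param solution a `charge_solution`.
#' @return dimensionless defect.
#' @export
charge_neutrality <- function(solution) {
  ctx <- solution$context
  abs(sum(solution$rho * ctx$area)) / sum(abs(solution$rho) * ctx$area)
}

#' Total potential at arbitrary points
#'
#' `phi(r) = phi^i(r) + (1/4 pi) sum_m rho_m [A_m / |r - r_m|]` with the
#' point kernel replaced by the analytic flat-triangle integral for facets
#' within `near_factor` mesh lengths (finite on facet interiors, e.g. at
#' electrode centroids).
#'
#' @param solution a `charge_solution`.
#' @param points N x 3 evaluation points (meters).
#' @param near_factor near-field radius in local mesh lengths; `0` disables
#'   the near-field treatment (then evaluation within 1e-9 m of a facet
#'   centroid is an error).
#' @return numeric vector of potentials (V).
#' @export
surface_potential <- function(solution, points, near_factor = 3) {
  points <- rbind_points(points)
  ctx <- solution$context
  if (near_factor <= 0) {
    d2min <- min_dist2_to_set(points, ctx$cent)
    if (any(d2min < 1e-18))
      stop("surface_potential: evaluation within 1e-9 m of a facet centroid (enable near_factor)")
  }
  sec <- cb_potential(points, ctx$V, ctx$F, ctx$cent, ctx$area, solution$rho,
                      ctx$len, near_factor)
  impressed_potential(solution$source, points) + sec
}

min_dist2_to_set <- function(points, set) {
  vapply(seq_len(nrow(points)), function(i)
    min(rowSums(sweep(set, 2, points[i, ])^2)), numeric(1))
}

#' Total electric field at interior points
#'
#' Impressed plus induced-charge field, point-kernel evaluation (keep points
#' a mesh length away from all interfaces).
#' @param solution a `charge_solution`.
#' @param points N x 3 points (meters).
#' @return N x 3 field matrix (V/m).
#' @export
electric_field <- function(solution, points) {
  points <- rbind_points(points)
  ctx <- solution$context
  sec <- cb_field_vec(points, ctx$cent, solution$rho * ctx$area)
  impressed_field(solution$source, points) + sec
}

#' Sample electrode voltages from a charge solution
#'
#' The voltage of each electrode is the total surface potential at the
#' centroid of its assigned skin facet.
#'
#' @param solution a `charge_solution`.
#' @param electrodes an `electrode_array` assigned to the model's skin
#'   (outermost) interface.
#' @param reference `"infinity"` (default) or `"average"`.
#' @return an `eeg_sample`: numeric voltage vector (V) with electrode labels
#'   and a `reference` attribute.
#' @export
electrode_voltages <- function(solution, electrodes, reference = c("infinity", "average")) {
  reference <- match.arg(reference)
  ctx <- solution$context
  skin <- solution$model$interfaces[[1]]
  nskin <- nrow(skin$faces)
  fi <- electrodes$facet_index
  if (any(fi < 1L | fi > nskin))
    stop("electrode assigned to a non-skin facet index")
  pts <- skin$centroid[fi, , drop = FALSE]
  v <- surface_potential(solution, pts)
  out <- eeg_sample(v, labels = electrodes$labels, reference = "infinity")
  if (reference == "average") out <- avg_reference(out)
  out
}

#' EEG single-sample container
#' @param voltages numeric vector (V).
#' @param labels electrode labels.
#' @param reference `"infinity"` or `"average"`.
#' @return an `eeg_sample`.
#' @export
eeg_sample <- function(voltages, labels = NULL, reference = "infinity") {
  structure(as.numeric(voltages),
            labels = labels %||% paste0("E", seq_along(voltages)),
            reference = reference, class = "eeg_sample")
}

#' Re-reference an EEG sample to the channel average
#'
#' Idempotent; the result sums to zero.
#' @param eeg an `eeg_sample` (or bare numeric vector).
#' @return average-referenced `eeg_sample`.
#' @export
avg_reference <- function(eeg) {
  v <- as.numeric(eeg) - mean(as.numeric(eeg))
  eeg_sample(v, labels = attr(eeg, "labels"), reference = "average")
}

#' @export
print.eeg_sample <- function(x, ...) {
  cat(sprintf("eeg_sample: %d channels (%s reference), range [%.3g, %.3g] uV\n",
              length(x), attr(x, "reference"),
              min(x) * 1e6, max(x) * 1e6))
  invisible(x)
}
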