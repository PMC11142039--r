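#' Cached forward factorization for dipole fitting
#'
#' Assembles and LU-factorizes the dense collocation operator of a (small)
#' 3-layer inverse model once, so that lead fields at arbitrary source
#' positions cost only back-substitutions.  The inverse forward model never
#' uses AMR.
#'
#' @param model3 a 3-layer `head_model`.
#' @param electrodes an `electrode_array` on its skin interface.
#' @return an object of class `lead_field_context`.
#' @export
lead_field_context <- function(model3, electrodes) {
  ctx <- forward_context(model3)
  A <- dense_operator(ctx)
  M <- nrow(A)
  D <- matrix(0, M, M)
  for (i in seq_along(ctx$nfacets)) {
    idx <- which(ctx$iface == i)
    a <- ctx$area[idx]
    D[idx, idx] <- matrix(1, length(idx), 1) %*% (a / sum(a))
  }
  P <- diag(M) - D
  qrB <- qr(P %*% A %*% P + D, LAPACK = TRUE)
  brain <- model3$interfaces[[length(model3$interfaces)]]
  sigma_brain <- model3$sigma_in[length(model3$interfaces)]
  epts <- model3$interfaces[[1]]$centroid[electrodes$facet_index, , drop = FALSE]
  structure(list(model = model3, ctx = ctx, qrB = qrB, P = P,
                 electrodes = electrodes, epoints = epts,
                 brain = brain, sigma_brain = sigma_brain),
            class = "lead_field_context")
}

as_lf_context <- function(model3, electrodes) {
  if (inherits(model3, "lead_field_context")) model3
  else lead_field_context(model3, electrodes)
}

# solve the deflated dense system for one or more RHS columns
lf_solve <- function(lfc, B) {
  B <- as.matrix(B)
  rhs <- lfc$P %*% B
  qr.coef(lfc$qrB, rhs)
}

#' Lead field matrix at a source position
#'
#' Column j holds the electrode voltages generated by a unit dipole moment
#' along Cartesian axis j at `position`, computed with the charge-based
#' solver of the 3-layer inverse model (no AMR).
#'
#' @param position length-3 source position (meters), inside the BRAIN
#'   region.
#' @param model3 a 3-layer `head_model` or a prebuilt `lead_field_context`.
#' @param electrodes an `electrode_array` (ignored when `model3` is a
#'   context).
#' @return E x 3 matrix (V per A m).
#' @export
lead_field <- function(position, model3, electrodes = NULL) {
  lfc <- as_lf_context(model3, electrodes)
  position <- as.numeric(position)
  if (!points_inside(position, lfc$brain))
    stop("source position outside the BRAIN region")
  ctx <- lfc$ctx
  L <- matrix(0, nrow(lfc$epoints), 3)
  rhoM <- matrix(0, nrow(ctx$cent), 3)
  for (j in 1:3) {
    m <- c(0, 0, 0); m[j] <- 1
    dp <- dipole(position, m, sigma_local = lfc$sigma_brain)
    Ei <- impressed_field(dp, ctx$cent)
    b <- ctx$K * rowSums(Ei * ctx$nrm)
    b <- deflate_monopole(ctx, b)
    rhoM[, j] <- lf_solve(lfc, b)
  }
  for (j in 1:3) {
    m <- c(0, 0, 0); m[j] <- 1
    dp <- dipole(position, m, sigma_local = lfc$sigma_brain)
    sec <- cb_potential(lfc$epoints, ctx$V, ctx$F, ctx$cent, ctx$area,
                        rhoM[, j], ctx$len, ctx$near_factor)
    L[, j] <- impressed_potential(dp, lfc$epoints) + sec
  }
  L
}

#' Linear moment fit and residual variance
#'
#' Least-squares moment for a fixed source position:
#' `q = argmin ||V - L q||_2` via orthogonal (QR) factorization, and the
#' residual variance `RV = ||V - L q||^2 / ||V||^2`, the fraction of EEG
#' variance the dipole leaves unexplained.
#'
#' @param L E x 3 lead field matrix (full column rank).
#' @param V EEG voltage vector (length E).
#' @return list with `moment` (length 3) and `rv`.
#' @export
fit_moment <- function(L, V) {
  V <- as.numeric(V)
  qrL <- qr(L)
  if (qrL$rank < ncol(L)) stop("rank-deficient lead field matrix")
  q <- qr.coef(qrL, V)
  resid <- V - as.numeric(L %*% q)
  list(moment = as.numeric(q), rv = sum(resid^2) / sum(V^2))
}

# least-squares moment via LAPACK QR without the rank gate, for use inside
# search loops where a numerically degenerate position must not abort
fit_moment_safe <- function(L, V) {
  tryCatch(fit_moment(L, V), error = function(e) {
    q <- qr.coef(qr(L, LAPACK = TRUE), V)
    q[is.na(q)] <- 0
    resid <- V - as.numeric(L %*% q)
    list(moment = as.numeric(q), rv = sum(resid^2) / sum(V^2))
  })
}

#' Residual-variance grid search for a seed position
#'
#' Evaluates the best-fitting single dipole on a Cartesian grid of the
#' stated spacing clipped to the interior of the SKULL surface, and returns
#' the grid point with the smallest residual variance (ties resolve to the
#' lexicographically smallest (x, y, z)).
#'
#' @param model3 3-layer `head_model` or `lead_field_context`.
#' @param V EEG sample (same electrodes as the context).
#' @param resolution_mm grid spacing in millimeters (default 5).
#' @param electrodes electrode array (when `model3` is a model).
#' @param margin_mm keep-out distance from the skull surface (default half
#'   the spacing).
#' @return list with `position` (best grid point), `rv`, `grid` (the full
#'   data.frame of evaluated points and RVs).
#' @export
grid_search <- function(model3, V, resolution_mm = 5, electrodes = NULL,
                        margin_mm = resolution_mm / 2) {
  if (resolution_mm <= 0) stop("resolution_mm must be > 0")
  lfc <- as_lf_context(model3, electrodes)
  skull <- lfc$model$interfaces[[2]]
  h <- resolution_mm / 1000
  rng <- apply(skull$vertices, 2, range)
  # lattice anchored at integer multiples of the spacing
  axis_seq <- function(lo, hi) seq(ceiling(lo / h) * h, hi, by = h)
  gx <- axis_seq(rng[1, 1], rng[2, 1])
  gy <- axis_seq(rng[1, 2], rng[2, 2])
  gz <- axis_seq(rng[1, 3], rng[2, 3])
  # lexicographic ordering (x fastest) fixes the tie rule
  grid <- as.matrix(expand.grid(x = gx, y = gy, z = gz))
  inside <- points_inside(grid, skull) & points_inside(grid, lfc$brain)
  grid <- grid[inside, , drop = FALSE]
  # enforce the keep-out margin from the brain surface so lead fields stay
  # well-defined
  if (margin_mm > 0) {
    keep <- grid_margin_ok(grid, lfc$brain, margin_mm / 1000)
    grid <- grid[keep, , drop = FALSE]
  }
  if (nrow(grid) == 0L) stop("empty source grid: spacing too coarse for the model")
  rvs <- vapply(seq_len(nrow(grid)), function(i) {
    L <- lead_field(grid[i, ], lfc)
    fit_moment_safe(L, as.numeric(V))$rv
  }, numeric(1))
  ord <- order(rvs, grid[, 1], grid[, 2], grid[, 3])
  best <- ord[1]
  list(position = as.numeric(grid[best, ]), rv = rvs[best],
       grid = data.frame(grid, rv = rvs))
}

grid_margin_ok <- function(points, surface, margin) {
  vapply(seq_len(nrow(points)), function(i) {
    min(sqrt(rowSums(sweep(surface$centroid, 2, points[i, ])^2))) > margin
  }, logical(1))
}

#' Nonlinear single-dipole fit
#'
#' Derivative-free (Nelder-Mead) refinement of the source position with a
#' nested linear moment fit; positions escaping the BRAIN region are
#' penalized with RV = 2.  Fully deterministic given `V`.
#'
#' @param seed length-3 starting position (meters), inside BRAIN.
#' @param model3 3-layer `head_model` or `lead_field_context`.
#' @param V the EEG sample to fit.
#' @param electrodes electrode array (when `model3` is a model).
#' @param max_evals function-evaluation budget (default 2000).
#' @param strategy label recorded in the result (`"truth-seed"` or
#'   `"grid-seed"`).
#' @return an object of class `dipole_fit`: `position`, `moment`, `rv`,
#'   `n_evals`, `seed_position`, `strategy`, `truncated`, plus the data and
#'   context needed by its methods.
#' @export
nonlinear_fit <- function(seed, model3, V, electrodes = NULL,
                          max_evals = 2000L, strategy = "truth-seed") {
  lfc <- as_lf_context(model3, electrodes)
  seed <- as.numeric(seed)
  if (!points_inside(seed, lfc$brain)) stop("seed position outside BRAIN")
  Vnum <- as.numeric(V)
  n_evals <- 0L
  objective <- function(p) {
    n_evals <<- n_evals + 1L
    if (!points_inside(p, lfc$brain)) return(2)
    L <- lead_field(p, lfc)
    # numerically rank-deficient lead fields (degenerate positions) are
    # penalized like out-of-region ones rather than aborting the search
    tryCatch(fit_moment(L, Vnum)$rv, error = function(e) 2)
  }
  # two Nelder-Mead sweeps: a full-scale pass, then a restart from the
  # optimum with a 0.1 mm simplex to polish below the position tolerance
  opt <- stats::optim(seed, objective, method = "Nelder-Mead",
                      control = list(maxit = max_evals, reltol = 1e-9,
                                     parscale = rep(5e-3, 3)))
  opt2 <- stats::optim(opt$par, objective, method = "Nelder-Mead",
                       control = list(maxit = max(100L, max_evals - opt$counts[1]),
                                      reltol = 1e-10, parscale = rep(1e-4, 3)))
  best <- if (opt2$value <= opt$value) opt2 else opt
  L <- lead_field(best$par, lfc)
  fm <- fit_moment_safe(L, Vnum)
  structure(list(position = as.numeric(best$par), moment = fm$moment,
                 rv = fm$rv, n_evals = n_evals, seed_position = seed,
                 strategy = strategy,
                 truncated = n_evals >= max_evals,
                 V = Vnum, L = L, lfc = lfc), class = "dipole_fit")
}

#' Single-dipole source reconstruction
#'
#' The front-end fitting function: reconstructs one current dipole from a
#' single EEG sample using a 3-layer inverse head model.  Two seeding
#' strategies are available -- starting from a known true position
#' (`"truth"`) and from the best point of a residual-variance grid search
#' (`"grid"`); with `strategy = "both"` the fit with the smaller residual
#' variance is reported.
#'
#' @param V an `eeg_sample` (or numeric vector) of electrode voltages.
#' @param model3 a 3-layer `head_model` or `lead_field_context`.
#' @param electrodes electrode array (when `model3` is a model).
#' @param strategy `"grid"`, `"truth"`, or `"both"`.
#' @param true_position length-3 position seeding the truth strategy.
#' @param resolution_mm grid spacing for the grid strategy (default 5).
#' @param max_evals Nelder-Mead evaluation budget per fit.
#' @return a `dipole_fit` (see [nonlinear_fit()]).
#' @examples
#' \dontrun{
#' m3 <- build_phantom_3(n_subdiv = 2)
#' el <- project_to_skin(fibonacci_layout(64), m3$interfaces[[1]])
#' dp <- dipole(c(0, 0, 0.055), c(1e-8, 0, 1e-8))
#' V <- electrode_voltages(solve_charges(m3, dp), el)
#' fit <- fit_dipole(V, m3, el, strategy = "truth", true_position = dp$position)
#' summary(fit)
#' }
#' @export
fit_dipole <- function(V, model3, electrodes = NULL,
                       strategy = c("both", "grid", "truth"),
                       true_position = NULL, resolution_mm = 5,
                       max_evals = 2000L) {
  strategy <- match.arg(strategy)
  lfc <- as_lf_context(model3, electrodes)
  fits <- list()
  if (strategy %in% c("both", "truth")) {
    if (is.null(true_position))
      stop("true_position is required for the truth-seeded strategy")
    fits$truth <- nonlinear_fit(true_position, lfc, V, max_evals = max_evals,
                                strategy = "truth-seed")
  }
  if (strategy %in% c("both", "grid")) {
    gs <- grid_search(lfc, V, resolution_mm = resolution_mm)
    fit <- nonlinear_fit(gs$position, lfc, V, max_evals = max_evals,
                         strategy = "grid-seed")
    if (fit$rv > gs$rv) {
      # the refinement must never report worse than its seed
      L <- lead_field(gs$position, lfc)
      fm <- fit_moment(L, as.numeric(V))
      fit$position <- gs$position; fit$moment <- fm$moment; fit$rv <- fm$rv
      fit$L <- L
    }
    fits$grid <- fit
  }
  rvs <- vapply(fits, `[[`, numeric(1), "rv")
  fits[[which.min(rvs)]]
}

#' Localization error metrics against a reference dipole
#'
#' Distance `||p0 - p1||` in millimeters and the unfolded angle (0-180
#' degrees) between the reference and fitted moments.
#'
#' @param true a `dipole` (the reference).
#' @param fit a `dipole_fit` (or any list with `position` and `moment`).
#' @return list with `distance_mm`, `angle_deg`, `rv`.
#' @export
error_metrics <- function(true, fit) {
  if (sum(true$moment^2) == 0 || sum(fit$moment^2) == 0)
    stop("both moments must be nonzero")
  d <- sqrt(sum((true$position - fit$position)^2)) * 1e3
  cosang <- sum(true$moment * fit$moment) /
    (sqrt(sum(true$moment^2)) * sqrt(sum(fit$moment^2)))
  ang <- acos(pmin(1, pmax(-1, cosang))) * 180 / pi
  list(distance_mm = d, angle_deg = ang, rv = fit$rv %||% NA_real_)
}

# ---- dipole_fit methods ------------------------------------------------------

#' @export
print.dipole_fit <- function(x, ...) {
  cat(sprintf("dipole_fit (%s): position (%.2f, %.2f, %.2f) mm, |q| = %.3g nA m, RV = %.3g\n",
              x$strategy, x$position[1] * 1e3, x$position[2] * 1e3,
              x$position[3] * 1e3, sqrt(sum(x$moment^2)) * 1e9, x$rv))
  invisible(x)
}

#' @export
summary.dipole_fit <- function(object, ...) {
  cat("Single-dipole fit (charge-based BEM, 3-layer inverse model)\n")
  cat(sprintf("  strategy      : %s\n", object$strategy))
  cat(sprintf("  seed position : (%.2f, %.2f, %.2f) mm\n",
              object$seed_position[1] * 1e3, object$seed_position[2] * 1e3,
              object$seed_position[3] * 1e3))
  cat(sprintf("  position      : (%.2f, %.2f, %.2f) mm\n",
              object$position[1] * 1e3, object$position[2] * 1e3,
              object$position[3] * 1e3))
  cat(sprintf("  moment        : (%.3g, %.3g, %.3g) nA m\n",
              object$moment[1] * 1e9, object$moment[2] * 1e9, object$moment[3] * 1e9))
  cat(sprintf("  residual var. : %.4g\n", object$rv))
  cat(sprintf("  evaluations   : %d%s\n", object$n_evals,
              if (object$truncated) " (budget exhausted)" else ""))
  invisible(object)
}

#' @export
coef.dipole_fit <- function(object, ...) {
  c(x = object$position[1], y = object$position[2], z = object$position[3],
    qx = object$moment[1], qy = object$moment[2], qz = object$moment[3])
}

#' @export
predict.dipole_fit <- function(object, ...) {
  as.numeric(object$L %*% object$moment)
}

#' @export
residuals.dipole_fit <- function(object, ...) {
  object$V - predict(object)
}
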