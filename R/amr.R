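#' Per-facet refinement cost
#'
#' The AMR cost of facet m is the total charge magnitude it carries,
#' `C_m = |rho_m| * A_m`; facets on non-refinable interfaces (the skin) are
#' masked to zero.
#'
#' @param solution a `charge_solution`.
#' @return nonnegative per-facet cost vector (refinable facets only carry
#'   nonzero cost).
#' @export
facet_costs <- function(solution) {
  ctx <- solution$context
  cost <- abs(solution$rho) * ctx$area
  refinable <- solution$model$refinable[ctx$iface]
  cost[!refinable] <- 0
  attr(cost, "refinable") <- refinable
  cost
}

#' Select the top cost fraction of refinable facets
#'
#' Returns the indices of the `ceiling(fraction * M_refinable)` largest
#' costs among refinable facets, pooled across interfaces; ties resolve to
#' the lower facet index.
#'
#' @param costs per-facet costs (with optional `refinable` attribute; by
#'   default every facet is eligible).
#' @param fraction fraction in (0, 1] (default 0.01, the top 1 percent).
#' @param refinable optional logical mask overriding the attribute.
#' @return integer vector of selected (global) facet indices.
#' @export
select_top_fraction <- function(costs, fraction = 0.01, refinable = NULL) {
  if (!(fraction > 0 && fraction <= 1)) stop("fraction must be in (0, 1]")
  refinable <- refinable %||% attr(costs, "refinable") %||% rep(TRUE, length(costs))
  eligible <- which(refinable)
  k <- ceiling(fraction * length(eligible))
  ord <- eligible[order(-costs[eligible], eligible)]
  sort(ord[seq_len(k)])
}

#' Adaptive mesh refinement loop
#'
#' Iterates solve -> cost -> top-fraction selection -> 4-way subdivision ->
#' re-solve until the relative change in electrode voltages between
#' consecutive steps, `||V_k - V_{k-1}||_2 / ||V_{k-1}||_2`, drops below
#' `threshold` (default 1 percent), or `max_steps` refinements have been
#' performed.  The skin interface is never refined (it is the observation
#' surface), so the electrode-facet assignment stays valid throughout.  Each
#' re-solve is warm-started from the parent solution with children
#' inheriting the parent charge density.
#'
#' @param model a `head_model` whose outermost interface is non-refinable.
#' @param source a `dipole` (or `uniform_field`).
#' @param electrodes an `electrode_array` on the skin interface.
#' @param threshold stopping threshold on the voltage change ratio
#'   (default 0.01).
#' @param fraction cost fraction refined per step (default 0.01).
#' @param max_steps maximum number of refinement steps (default 15).
#' @param tol,method,backend forwarded to [solve_charges()].
#' @param reference voltage reference for the recorded EEG samples.
#' @param verbose print a per-step trace line.
#' @return an object of class `amr_state`: final `model`, final `solution`,
#'   `voltages` (final `eeg_sample`), `voltage_history` (list),
#'   `rel_change_history`, `steps` performed, `converged`, and a `trace`
#'   data.frame (step, facets, selected, rel_change).
#' @export
amr_loop <- function(model, source, electrodes, threshold = 0.01,
                     fraction = 0.01, max_steps = 15L, tol = 1e-6,
                     method = "auto", backend = getOption("chargebem.backend", "compiled"),
                     reference = "infinity", verbose = FALSE) {
  if (threshold <= 0) stop("threshold must be > 0")
  if (max_steps < 1L) stop("max_steps must be >= 1")
  if (model$refinable[1])
    stop("the outermost (skin) interface must be non-refinable")
  sol <- solve_charges(model, source, tol = tol, method = method, backend = backend)
  V <- electrode_voltages(sol, electrodes, reference = reference)
  vh <- list(V)
  rel <- numeric(0)
  trace <- data.frame(step = 0L, facets = length(sol$rho), selected = NA_integer_,
                      rel_change = NA_real_)
  converged <- FALSE
  steps <- 0L
  for (k in seq_len(max_steps)) {
    costs <- facet_costs(sol)
    sel <- select_top_fraction(costs, fraction)
    model2 <- refine_model(model, sol$context, sel)
    warm <- prolong_rho(sol, sel)
    sol2 <- tryCatch(
      solve_charges(model2, source, tol = tol, method = method,
                    backend = backend, warm_start = warm),
      error = function(e) stop("solver failure at AMR step ", k, ": ",
                               conditionMessage(e)))
    V2 <- electrode_voltages(sol2, electrodes, reference = reference)
    r <- sqrt(sum((as.numeric(V2) - as.numeric(V))^2)) / sqrt(sum(as.numeric(V)^2))
    rel <- c(rel, r)
    vh[[length(vh) + 1L]] <- V2
    trace <- rbind(trace, data.frame(step = k, facets = length(sol2$rho),
                                     selected = length(sel), rel_change = r))
    if (verbose)
      message(sprintf("AMR step %2d: %6d facets (+%d refined), rel change %.4g",
                      k, length(sol2$rho), length(sel), r))
    model <- model2
    sol <- sol2
    V <- V2
    steps <- k
    if (r < threshold) { converged <- TRUE; break }
  }
  if (!converged)
    warning(sprintf("AMR truncated at max_steps = %d (last ratio %.3g >= threshold %.3g)",
                    max_steps, rel[length(rel)], threshold))
  structure(list(model = model, solution = sol, voltages = V,
                 voltage_history = vh, rel_change_history = rel,
                 steps = steps, converged = converged, trace = trace),
            class = "amr_state")
}

#' @export
print.amr_state <- function(x, ...) {
  cat(sprintf("amr_state: %d refinement steps, %s, final rel change %.4g, %d facets\n",
              x$steps, if (x$converged) "converged" else "truncated",
              if (length(x$rel_change_history)) utils::tail(x$rel_change_history, 1) else NA,
              length(x$solution$rho)))
  invisible(x)
}

# subdivide the selected global facet indices on their owning interfaces
refine_model <- function(model, ctx, sel) {
  off <- ctx$offsets
  nf <- ctx$nfacets
  out <- model
  for (i in seq_along(model$interfaces)) {
    local <- sel[sel > off[i] & sel <= off[i] + nf[i]] - off[i]
    if (length(local))
      out$interfaces[[i]] <- subdivide_facets(model$interfaces[[i]], local)
  }
  out
}

# warm start: children inherit the parent facet's charge density.  Child
# ordering must match refine_model/subdivide_facets: first child replaces
# the parent slot, the remaining three are appended per interface in
# selection order.
prolong_rho <- function(sol, sel) {
  ctx <- sol$context
  off <- ctx$offsets
  nf <- ctx$nfacets
  pieces <- vector("list", length(nf))
  for (i in seq_along(nf)) {
    idx <- off[i] + seq_len(nf[i])
    rho_i <- sol$rho[idx]
    local <- sel[sel > off[i] & sel <= off[i] + nf[i]] - off[i]
    if (length(local)) {
      appended <- rep(rho_i[local], 3L)
      rho_i <- c(rho_i, appended)
    }
    pieces[[i]] <- rho_i
  }
  unlist(pieces, use.names = FALSE)
}
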