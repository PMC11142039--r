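#' Fibonacci cap electrode layout
#'
#' Deterministic, near-uniform unit directions on the upper spherical cap
#' covering `cap_fraction` of the full sphere (emulating scalp coverage
#' while sparing the face/neck region); the replacement for semi-manual
#' electrode placement, which needs anatomical landmarks a phantom lacks.
#'
#' @param n number of electrodes (>= 4; default 256).
#' @param cap_fraction fraction of the sphere covered by the cap, in
#'   (0, 1] (default 0.65).
#' @return n x 3 matrix of unit direction vectors (cap pole at +z).
#' @export
fibonacci_layout <- function(n = 256L, cap_fraction = 0.65) {
  if (n < 4L) stop("n must be >= 4")
  if (!(cap_fraction > 0 && cap_fraction <= 1)) stop("cap_fraction must be in (0, 1]")
  golden <- pi * (3 - sqrt(5))
  i <- seq_len(n) - 0.5
  # uniform in z over [1 - 2 * cap_fraction, 1]
  z <- 1 - 2 * cap_fraction * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  th <- golden * (seq_len(n) - 1L)
  cbind(r * cos(th), r * sin(th), z)
}

#' Project electrode directions onto the skin mesh
#'
#' Each direction (ray from the skin-mesh center) is assigned to the skin
#' facet it intersects; the electrode position is that facet's centroid.
#' Ties (a ray hitting an edge shared by facets) resolve to the lowest facet
#' index.
#'
#' @param directions n x 3 matrix of unit vectors.
#' @param skin closed `trimesh` (the skin interface).
#' @param labels optional electrode labels (default `E1..En`).
#' @return an `electrode_array`: list with `labels`, `positions` (n x 3,
#'   meters), `facet_index` (per electrode, into the skin facet list).
#' @export
project_to_skin <- function(directions, skin, labels = NULL) {
  directions <- rbind_points(directions)
  directions <- directions / sqrt(rowSums(directions^2))
  center <- skin$center %||% colMeans(skin$vertices)
  idx <- ray_facet_index(directions, skin, center)
  positions <- skin$centroid[idx, , drop = FALSE]
  electrode_array(labels %||% paste0("E", seq_len(nrow(directions))),
                  positions, idx)
}

# nearest ray-facet intersection; falls back to best-aligned centroid for
# rays that slip through facet edge gaps
ray_facet_index <- function(directions, mesh, center) {
  V <- mesh$vertices
  F <- mesh$faces
  cent <- sweep(mesh$centroid, 2, center)
  vapply(seq_len(nrow(directions)), function(e) {
    d <- directions[e, ]
    hit <- ray_triangle_hits(center, d, V, F)
    if (length(hit$idx)) hit$idx[which.min(hit$t)]
    else {
      cd <- as.numeric(cent %*% d) / sqrt(rowSums(cent^2))
      which.max(cd)
    }
  }, integer(1))
}

ray_triangle_hits <- function(origin, dir, V, F) {
  # Moller-Trumbore, vectorized over facets
  v0 <- V[F[, 1], , drop = FALSE]
  e1 <- V[F[, 2], , drop = FALSE] - v0
  e2 <- V[F[, 3], , drop = FALSE] - v0
  h <- cbind(dir[2] * e2[, 3] - dir[3] * e2[, 2],
             dir[3] * e2[, 1] - dir[1] * e2[, 3],
             dir[1] * e2[, 2] - dir[2] * e2[, 1])
  a <- rowSums(e1 * h)
  s <- -sweep(v0, 2, origin)
  u <- rowSums(s * h) / a
  q <- cbind(s[, 2] * e1[, 3] - s[, 3] * e1[, 2],
             s[, 3] * e1[, 1] - s[, 1] * e1[, 3],
             s[, 1] * e1[, 2] - s[, 2] * e1[, 1])
  v <- as.numeric(q %*% dir) / a
  t <- rowSums(e2 * q) / a
  ok <- is.finite(a) & abs(a) > 1e-300 & u >= -1e-12 & v >= -1e-12 &
    (u + v) <= 1 + 1e-12 & t > 0
  list(idx = which(ok), t = t[ok])
}

#' Electrode array container
#' @param labels unique electrode labels.
#' @param positions n x 3 positions (meters).
#' @param facet_index skin-facet assignment per electrode.
#' @return an `electrode_array`.
#' @export
electrode_array <- function(labels, positions, facet_index) {
  if (anyDuplicated(labels)) stop("electrode labels must be unique")
  structure(list(labels = as.character(labels),
                 positions = rbind_points(positions),
                 facet_index = as.integer(facet_index)),
            class = "electrode_array")
}

#' @export
print.electrode_array <- function(x, ...) {
  cat(sprintf("electrode_array: %d electrodes on %d distinct skin facets\n",
              length(x$labels), length(unique(x$facet_index))))
  invisible(x)
}

#' Read / write electrode layouts
#'
#' Plain-text whitespace-separated `label x y z` with coordinates in
#' millimeters.
#' @param path file path.
#' @return for `read_electrode_layout`, a data.frame with `label` and unit
#'   positions in mm; positions must be assigned to a skin mesh with
#'   [project_to_skin()] before use.
#' @export
read_electrode_layout <- function(path) {
  tab <- utils::read.table(path, col.names = c("label", "x", "y", "z"),
                           stringsAsFactors = FALSE)
  tab
}

#' @rdname read_electrode_layout
#' @param electrodes an `electrode_array`.
#' @export
write_electrode_layout <- function(electrodes, path) {
  tab <- data.frame(label = electrodes$labels,
                    x = electrodes$positions[, 1] * 1e3,
                    y = electrodes$positions[, 2] * 1e3,
                    z = electrodes$positions[, 3] * 1e3)
  utils::write.table(tab, path, quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Write an EEG sample as labeled plain text
#'
#' Two whitespace-separated columns: electrode label, voltage (V).
#' @param eeg an `eeg_sample`.
#' @param path output path.
#' @export
write_eeg <- function(eeg, path) {
  utils::write.table(data.frame(label = attr(eeg, "labels"),
                                value = as.numeric(eeg)),
                     path, quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
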