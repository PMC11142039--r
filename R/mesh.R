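#' Triangle surface meshes
#'
#' A `trimesh` is a watertight, outward-oriented triangle surface stored as a
#' list with `vertices` (V x 3 matrix, meters), `faces` (F x 3 integer matrix,
#' 1-based, counter-clockwise seen from outside), and per-facet geometry:
#' `centroid` (F x 3), `normal` (F x 3, unit outward), `area` (F, m^2).
#'
#' @param vertices numeric V x 3 matrix of vertex coordinates in meters.
#' @param faces integer F x 3 matrix of 1-based vertex indices.
#' @param reorient if `TRUE` (default) a closed mesh with negative signed
#'   volume is flipped to outward orientation with a warning.
#' @return an object of class `trimesh` with facet geometry populated.
#' @export
trimesh <- function(vertices, faces, reorient = TRUE) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3L || ncol(faces) != 3L)
    stop("vertices and faces must have 3 columns")
  if (nrow(faces) < 1L) stop("mesh has no faces")
  if (min(faces) < 1L || max(faces) > nrow(vertices))
    stop("faces reference invalid vertex indices")
  m <- structure(list(vertices = vertices, faces = faces),
                 class = "trimesh")
  m <- facet_geometry(m)
  if (reorient && signed_volume(m) < 0) {
    warning("mesh had inward orientation; reoriented to outward")
    m$faces <- m$faces[, c(1L, 3L, 2L), drop = FALSE]
    m <- facet_geometry(m)
  }
  m
}

#' @export
print.trimesh <- function(x, ...) {
  cat(sprintf("trimesh: %d vertices, %d facets, total area %.6g m^2\n",
              nrow(x$vertices), nrow(x$faces), sum(x$area)))
  invisible(x)
}

#' Per-facet centroids, outward normals and areas
#'
#' Centroid is the vertex mean, area half the cross-product norm, and the
#' normal the normalized cross product of the edge vectors (counter-clockwise
#' convention).
#'
#' @param mesh a `trimesh` (geometry fields are recomputed).
#' @return the mesh with `centroid`, `normal`, `area` populated.
#' @export
facet_geometry <- function(mesh) {
  V <- mesh$vertices
  F <- mesh$faces
  p1 <- V[F[, 1], , drop = FALSE]
  p2 <- V[F[, 2], , drop = FALSE]
  p3 <- V[F[, 3], , drop = FALSE]
  e1 <- p2 - p1
  e2 <- p3 - p1
  cr <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  nrm2 <- sqrt(rowSums(cr^2))
  scale <- sum(nrm2) / length(nrm2)
  bad <- which(nrm2 <= 1e-14 * scale)
  if (length(bad))
    stop(sprintf("degenerate (zero-area) facet(s): %s",
                 paste(utils::head(bad, 5L), collapse = ", ")))
  mesh$centroid <- (p1 + p2 + p3) / 3
  mesh$normal <- cr / nrm2
  mesh$area <- nrm2 / 2
  mesh
}

#' Signed volume enclosed by a closed oriented mesh
#'
#' Positive for outward orientation (divergence theorem on x/3).
#' @param mesh a `trimesh`.
#' @return scalar volume in m^3.
#' @export
signed_volume <- function(mesh) {
  V <- mesh$vertices
  F <- mesh$faces
  p1 <- V[F[, 1], , drop = FALSE]
  p2 <- V[F[, 2], , drop = FALSE]
  p3 <- V[F[, 3], , drop = FALSE]
  sum(p1[, 1] * (p2[, 2] * p3[, 3] - p2[, 3] * p3[, 2]) +
      p1[, 2] * (p2[, 3] * p3[, 1] - p2[, 1] * p3[, 3]) +
      p1[, 3] * (p2[, 1] * p3[, 2] - p2[, 2] * p3[, 1])) / 6
}

#' Closure defect of an oriented surface
#'
#' For a closed oriented surface the area-weighted normals sum to zero; the
#' returned defect `||sum A_m n_m|| / sum A_m` is ~0 (< 1e-9) for closed
#' meshes.
#' @param mesh a `trimesh`.
#' @return dimensionless closure defect.
#' @export
closure_defect <- function(mesh) {
  s <- colSums(mesh$normal * mesh$area)
  sqrt(sum(s^2)) / sum(mesh$area)
}

#' Geodesic icosphere
#'
#' Generates a closed, outward-oriented sphere mesh by recursive 4-way
#' subdivision of an icosahedron with vertex projection to the sphere;
#' `20 * 4^n_subdiv` facets.
#'
#' @param radius sphere radius in meters (> 0).
#' @param n_subdiv number of subdivision levels (>= 0).
#' @param center sphere center (length-3, meters).
#' @return a `trimesh`.
#' @examples
#' m <- icosphere(0.09, 2)
#' nrow(m$faces)  # 320
#' @export
icosphere <- function(radius, n_subdiv = 3L, center = c(0, 0, 0)) {
  if (!is.numeric(radius) || length(radius) != 1L || radius <= 0)
    stop("radius must be a positive scalar")
  if (n_subdiv < 0) stop("n_subdiv must be >= 0")
  phi <- (1 + sqrt(5)) / 2
  V <- rbind(
    c(-1,  phi, 0), c(1,  phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1,  phi), c(0, 1,  phi), c(0, -1, -phi), c(0, 1, -phi),
    c( phi, 0, -1), c( phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  V <- V / sqrt(rowSums(V^2))
  F <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  storage.mode(F) <- "integer"
  for (lev in seq_len(n_subdiv)) {
    nv <- nrow(V)
    edge_key <- function(a, b) ifelse(a < b, a * (nv + 1L) + b, b * (nv + 1L) + a)
    mid_cache <- new.env(hash = TRUE, parent = emptyenv())
    newV <- list()
    get_mid <- function(a, b) {
      k <- as.character(edge_key(a, b))
      idx <- mid_cache[[k]]
      if (!is.null(idx)) return(idx)
      p <- V[a, ] + V[b, ]
      p <- p / sqrt(sum(p^2))
      newV[[length(newV) + 1L]] <<- p
      idx <- nv + length(newV)
      mid_cache[[k]] <- idx
      idx
    }
    newF <- matrix(0L, nrow(F) * 4L, 3L)
    for (f in seq_len(nrow(F))) {
      a <- F[f, 1]; b <- F[f, 2]; c3 <- F[f, 3]
      ab <- get_mid(a, b); bc <- get_mid(b, c3); ca <- get_mid(c3, a)
      newF[4L * f - 3L, ] <- c(a, ab, ca)
      newF[4L * f - 2L, ] <- c(b, bc, ab)
      newF[4L * f - 1L, ] <- c(c3, ca, bc)
      newF[4L * f, ] <- c(ab, bc, ca)
    }
    V <- rbind(V, do.call(rbind, newV))
    F <- newF
  }
  V <- V * radius
  V <- sweep(V, 2, center, "+")
  m <- trimesh(V, F, reorient = FALSE)
  m$center <- as.numeric(center)
  m$radius <- radius
  m
}

#' Selective 4-way facet subdivision
#'
#' Replaces each selected facet by its four midpoint-congruent children
#' (midpoints are not snapped to any surface, so planar facet area is
#' preserved exactly).  Unselected facets keep their position in the facet
#' list; children are appended in selection order.  The result may be
#' non-conforming (hanging vertices), which facet-collocation solvers accept.
#'
#' @param mesh a `trimesh`.
#' @param facet_indices integer vector of unique 1-based facet indices.
#' @return the refined `trimesh`.
#' @export
subdivide_facets <- function(mesh, facet_indices) {
  facet_indices <- as.integer(facet_indices)
  if (length(facet_indices) == 0L) return(mesh)
  if (anyDuplicated(facet_indices))
    stop("facet_indices must be unique")
  if (min(facet_indices) < 1L || max(facet_indices) > nrow(mesh$faces))
    stop("facet index out of range")
  V <- mesh$vertices
  F <- mesh$faces
  sel <- facet_indices
  a <- F[sel, 1]; b <- F[sel, 2]; c3 <- F[sel, 3]
  mab <- (V[a, , drop = FALSE] + V[b, , drop = FALSE]) / 2
  mbc <- (V[b, , drop = FALSE] + V[c3, , drop = FALSE]) / 2
  mca <- (V[c3, , drop = FALSE] + V[a, , drop = FALSE]) / 2
  nv <- nrow(V)
  k <- length(sel)
  iab <- nv + seq_len(k)
  ibc <- nv + k + seq_len(k)
  ica <- nv + 2L * k + seq_len(k)
  Vnew <- rbind(V, mab, mbc, mca)
  child <- rbind(cbind(a, iab, ica),
                 cbind(b, ibc, iab),
                 cbind(c3, ica, ibc),
                 cbind(iab, ibc, ica))
  # first child replaces the parent in place, the rest are appended, so
  # unselected facet indices are preserved
  Fnew <- F
  Fnew[sel, ] <- child[seq_len(k), ]
  Fnew <- rbind(Fnew, child[-seq_len(k), , drop = FALSE])
  storage.mode(Fnew) <- "integer"
  out <- structure(list(vertices = Vnew, faces = Fnew), class = "trimesh")
  out <- facet_geometry(out)
  out$center <- mesh$center
  out$radius <- mesh$radius
  out
}

#' Points-inside test for a closed surface
#'
#' Generalized winding number (summed solid angles): ~1 inside, ~0 outside.
#' @param points N x 3 matrix (or length-3 vector) of query points.
#' @param mesh closed outward-oriented `trimesh`.
#' @return logical vector, `TRUE` for strictly inside points.
#' @export
points_inside <- function(points, mesh) {
  points <- rbind_points(points)
  w <- cb_winding(points, mesh$vertices, mesh$faces)
  w > 0.5
}

rbind_points <- function(points) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 3)
  points <- as.matrix(points)
  storage.mode(points) <- "double"
  points
}
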