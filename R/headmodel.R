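#' Tissue conductivity presets
#'
#' Loads the conductivity sets shipped with the package (file
#' `extdata/conductivities.tsv`): `VWB7`, `ITIS7`, `SIMNIBS7` for the
#' 5-layer (7-compartment) class and `VWB3`, `ITIS3`, `SIMNIBS3` for the
#' 3-layer class (tissues SKIN, SKULL, BRAIN).
#'
#' @param name preset name (case/punctuation tolerant: `"IT'IS7"`,
#'   `"itis7"`, ... all resolve to `ITIS7`).  With `name = NULL` all presets
#'   are returned as a data.frame.
#' @return a `conductivity_set`: named numeric vector of conductivities
#'   (S/m) with attribute `name`; or the full preset table.
#' @export
conductivity_set <- function(name = NULL) {
  path <- system.file("extdata", "conductivities.tsv", package = "chargebem")
  tab <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  if (is.null(name)) return(tab)
  key <- toupper(gsub("[^A-Za-z0-9]", "", name))
  rows <- tab[toupper(tab$set) == key, ]
  if (nrow(rows) == 0L)
    stop("unknown conductivity set: ", name, " (available: ",
         paste(unique(tab$set), collapse = ", "), ")")
  sig <- stats::setNames(rows$sigma, rows$tissue)
  if (any(sig <= 0)) stop("conductivities must be positive")
  structure(sig, name = key, class = "conductivity_set")
}

#' @export
print.conductivity_set <- function(x, ...) {
  cat("conductivity set", attr(x, "name"), "(S/m):\n")
  print(unclass(stats::setNames(as.numeric(x), names(x))))
  invisible(x)
}

#' Conductivity contrast at an interface
#'
#' `K = (sigma_in - sigma_out) / (sigma_in + sigma_out)`, the dimensionless
#' contrast that drives induced surface charge; `K = 1` against air
#' (`sigma_out = 0`).
#'
#' @param sigma_in conductivity inside the interface (S/m, > 0).
#' @param sigma_out conductivity outside (S/m, >= 0; 0 = air).
#' @return contrast in `[-1, 1]`.
#' @examples
#' contrast(0.010, 0.430)  # skull inside skin, VWB set
#' @export
contrast <- function(sigma_in, sigma_out) {
  if (any(sigma_in <= 0)) stop("sigma_in must be > 0")
  if (any(sigma_out < 0)) stop("sigma_out must be >= 0")
  if (any(sigma_in + sigma_out == 0)) stop("undefined contrast: both conductivities zero")
  (sigma_in - sigma_out) / (sigma_in + sigma_out)
}

#' Nested-interface head model
#'
#' Assembles closed interfaces (ordered outermost to innermost) with the
#' conductivities of the regions each separates, computing the per-interface
#' contrast `K`.  Consistency of the conductivity chain (sigma inside
#' interface i = sigma outside interface i+1) is enforced.
#'
#' @param interfaces list of `trimesh`, outermost first.
#' @param sigma_in,sigma_out conductivity (S/m) inside/outside each
#'   interface; `sigma_out[1]` may be 0 (air).
#' @param refinable logical per interface: eligible for adaptive refinement.
#' @param tissue optional tissue labels per interface.
#' @param check_nesting verify strict nesting (default `TRUE`).
#' @return an object of class `head_model`.
#' @export
head_model <- function(interfaces, sigma_in, sigma_out,
                       refinable = rep(TRUE, length(interfaces)),
                       tissue = NULL, check_nesting = TRUE) {
  n <- length(interfaces)
  stopifnot(length(sigma_in) == n, length(sigma_out) == n, length(refinable) == n)
  if (any(sigma_in <= 0)) stop("sigma_in must be > 0 for all interfaces")
  if (any(sigma_out < 0) || any(sigma_out[-1] <= 0))
    stop("sigma_out must be > 0 (interior) or >= 0 (outermost)")
  if (n > 1L && any(abs(sigma_in[-n] - sigma_out[-1]) >
                    1e-12 * (sigma_in[-n] + sigma_out[-1])))
    stop("conductivity chain inconsistent: sigma_in[i] must equal sigma_out[i+1]")
  model <- structure(list(
    interfaces = interfaces,
    sigma_in = as.numeric(sigma_in),
    sigma_out = as.numeric(sigma_out),
    K = contrast(sigma_in, sigma_out),
    refinable = as.logical(refinable),
    tissue = tissue %||% paste0("interface", seq_len(n))
  ), class = "head_model")
  if (check_nesting) {
    nc <- nesting_check(model)
    if (!nc$ok) stop("interfaces are not strictly nested: ", nc$violation)
  }
  model
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.head_model <- function(x, ...) {
  cat(sprintf("head_model: %d nested interfaces, %d facets total\n",
              length(x$interfaces), sum(facet_counts(x))))
  for (i in seq_along(x$interfaces))
    cat(sprintf("  %-10s %6d facets  sigma_in %.4g  sigma_out %.4g  K %+.4f%s\n",
                x$tissue[i], nrow(x$interfaces[[i]]$faces),
                x$sigma_in[i], x$sigma_out[i], x$K[i],
                if (x$refinable[i]) "" else "  [not refinable]"))
  invisible(x)
}

#' Facet counts per interface
#' @param model a `head_model`.
#' @return integer vector.
#' @export
facet_counts <- function(model) {
  vapply(model$interfaces, function(m) nrow(m$faces), integer(1))
}

#' Strict-nesting check
#'
#' Verifies that every vertex of interface i+1 lies strictly inside
#' interface i (winding-number point-in-surface test).
#'
#' @param model a `head_model`.
#' @return list with `ok` (logical) and `violation` (string or `NA`).
#' @export
nesting_check <- function(model) {
  n <- length(model$interfaces)
  for (i in seq_len(n - 1L)) {
    inner <- model$interfaces[[i + 1L]]$vertices
    inside <- points_inside(inner, model$interfaces[[i]])
    if (!all(inside)) {
      return(list(ok = FALSE, violation = sprintf(
        "vertex %d of interface %d is not inside interface %d",
        which(!inside)[1], i + 1L, i)))
    }
  }
  list(ok = TRUE, violation = NA_character_)
}

#' 5-layer nested-sphere head phantom
#'
#' Builds five nested icospheres (skin, skull, CSF -- i.e. the outer grey
#' matter boundary --, GM, WM) with contrasts computed against air outside
#' the skin.  The default radii place a thin 2 mm CSF-GM gap, the geometric
#' hazard that makes adaptive refinement necessary.  The skin interface is
#' marked non-refinable (it is the observation surface).
#'
#' @param radii_mm five strictly decreasing radii in millimeters
#'   (default `c(92, 86, 80, 78, 70)`).
#' @param conductivities a `conductivity_set` or preset name with tissues
#'   skin, skull, csf, gm, wm (default `"ITIS7"`).
#' @param n_subdiv icosphere subdivision level per interface (default 3).
#' @param center_offsets optional 5 x 3 matrix of per-shell center offsets
#'   in millimeters (breaks concentricity).
#' @return a `head_model`.
#' @export
build_phantom_5 <- function(radii_mm = c(92, 86, 80, 78, 70),
                            conductivities = "ITIS7", n_subdiv = 3L,
                            center_offsets = NULL) {
  build_phantom(radii_mm, conductivities, n_subdiv, center_offsets,
                tissues = c("skin", "skull", "csf", "gm", "wm"),
                refinable = c(FALSE, TRUE, TRUE, TRUE, TRUE))
}

#' 3-layer nested-sphere head phantom
#'
#' Shells SKIN, SKULL, BRAIN with the 3-layer conductivity presets; the
#' phantom analog of the decimated inverse models.  The default subdivision
#' level 4 gives 5120 facets per shell (15360 total), the phantom-resolution
#' counterpart of the ~3 x 14000-triangle decimated meshes.
#'
#' @param radii_mm three strictly decreasing radii in millimeters
#'   (default `c(92, 86, 80)`).
#' @param conductivities preset name or `conductivity_set` with tissues
#'   skin, skull, brain (default `"ITIS3"`).
#' @param n_subdiv subdivision level (default 4).
#' @param center_offsets optional 3 x 3 offsets in millimeters.
#' @return a `head_model`.
#' @export
build_phantom_3 <- function(radii_mm = c(92, 86, 80),
                            conductivities = "ITIS3", n_subdiv = 4L,
                            center_offsets = NULL) {
  build_phantom(radii_mm, conductivities, n_subdiv, center_offsets,
                tissues = c("skin", "skull", "brain"),
                refinable = c(FALSE, TRUE, TRUE))
}

build_phantom <- function(radii_mm, conductivities, n_subdiv, center_offsets,
                          tissues, refinable) {
  n <- length(tissues)
  if (length(radii_mm) != n || any(diff(radii_mm) >= 0))
    stop("radii_mm must be ", n, " strictly decreasing values")
  if (is.character(conductivities)) conductivities <- conductivity_set(conductivities)
  missing_t <- setdiff(tissues, names(conductivities))
  if (length(missing_t))
    stop("conductivity set lacks tissue(s): ", paste(missing_t, collapse = ", "))
  sig <- as.numeric(conductivities[tissues])
  if (is.null(center_offsets)) center_offsets <- matrix(0, n, 3)
  center_offsets <- as.matrix(center_offsets)
  if (length(n_subdiv) == 1L) n_subdiv <- rep(n_subdiv, n)
  meshes <- lapply(seq_len(n), function(i)
    icosphere(radii_mm[i] / 1000, n_subdiv[i], center_offsets[i, ] / 1000))
  head_model(meshes,
             sigma_in = sig,
             sigma_out = c(0, sig[-n]),
             refinable = refinable,
             tissue = tissues)
}

#' Region conductivity at points
#'
#' Conductivity of the compartment geometrically containing each point
#' (0 outside the outermost interface).
#'
#' @param model a `head_model`.
#' @param points N x 3 matrix or length-3 vector (meters).
#' @return numeric vector of conductivities (S/m).
#' @export
local_sigma <- function(model, points) {
  points <- rbind_points(points)
  sig <- rep(0, nrow(points))
  for (i in seq_along(model$interfaces)) {
    inside <- points_inside(points, model$interfaces[[i]])
    sig[inside] <- model$sigma_in[i]
  }
  sig
}
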