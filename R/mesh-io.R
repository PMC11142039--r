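#' Read a triangle mesh from STL, PLY or OFF
#'
#' Supports ASCII PLY, OFF, and both ASCII and binary little-endian STL.
#' Closed meshes are auto-reoriented to outward (positive signed volume) with
#' a warning.
#'
#' @param path file path.
#' @param format one of `"stl"`, `"ply"`, `"off"`; guessed from the file
#'   extension when missing.
#' @return a `trimesh`.
#' @export
read_mesh <- function(path, format = NULL) {
  if (!file.exists(path)) stop("file does not exist: ", path)
  format <- guess_format(path, format)
  switch(format,
         ply = read_ply(path),
         off = read_off(path),
         stl = read_stl(path),
         stop("unsupported mesh format: ", format))
}

#' Write a triangle mesh to STL, PLY or OFF
#'
#' @param mesh a `trimesh`.
#' @param path output path.
#' @param format one of `"stl"`, `"ply"`, `"off"`; guessed from the
#'   extension when missing.
#' @param binary for STL, write the binary little-endian variant
#'   (default `FALSE` = ASCII).
#' @return `path`, invisibly.
#' @export
write_mesh <- function(mesh, path, format = NULL, binary = FALSE) {
  format <- guess_format(path, format)
  switch(format,
         ply = write_ply(mesh, path),
         off = write_off(mesh, path),
         stl = if (binary) write_stl_bin(mesh, path) else write_stl_ascii(mesh, path),
         stop("unsupported mesh format: ", format))
  invisible(path)
}

guess_format <- function(path, format) {
  if (!is.null(format)) return(tolower(format))
  ext <- tolower(tools::file_ext(path))
  if (!ext %in% c("stl", "ply", "off"))
    stop("cannot guess mesh format from extension: ", path)
  ext
}

parse_fail <- function(path, line, msg) {
  stop(sprintf("parse error in %s at line %d: %s", path, line, msg))
}

read_ply <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 1L || trimws(lines[1]) != "ply")
    parse_fail(path, 1L, "not a PLY file (missing 'ply' magic)")
  nv <- nf <- NA_integer_
  i <- 2L
  while (i <= length(lines)) {
    tok <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(tok) >= 1L && tok[1] == "format" && tok[2] != "ascii")
      parse_fail(path, i, "only ascii PLY is supported")
    if (length(tok) >= 3L && tok[1] == "element") {
      if (tok[2] == "vertex") nv <- as.integer(tok[3])
      if (tok[2] == "face") nf <- as.integer(tok[3])
    }
    if (length(tok) >= 1L && tok[1] == "end_header") break
    i <- i + 1L
  }
  if (i > length(lines)) parse_fail(path, length(lines), "missing end_header")
  if (is.na(nv) || is.na(nf)) parse_fail(path, i, "missing element counts")
  body <- lines[(i + 1L):length(lines)]
  if (length(body) < nv + nf) parse_fail(path, length(lines), "truncated body")
  V <- matrix(scan(text = body[seq_len(nv)], quiet = TRUE), nv, byrow = TRUE)[, 1:3, drop = FALSE]
  Fraw <- lapply(seq_len(nf), function(k) {
    tok <- as.integer(strsplit(trimws(body[nv + k]), "\\s+")[[1]])
    if (tok[1] != 3L) parse_fail(path, i + nv + k, "non-triangular face")
    tok[2:4] + 1L
  })
  trimesh(V, do.call(rbind, Fraw))
}

write_ply <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               sprintf("element vertex %d", nrow(mesh$vertices)),
               "property double x", "property double y", "property double z",
               sprintf("element face %d", nrow(mesh$faces)),
               "property list uchar int vertex_indices",
               "end_header"), con)
  writeLines(apply(mesh$vertices, 1, function(v)
    sprintf("%.17g %.17g %.17g", v[1], v[2], v[3])), con)
  writeLines(apply(mesh$faces - 1L, 1, function(f)
    sprintf("3 %d %d %d", f[1], f[2], f[3])), con)
}

read_off <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  if (length(lines) < 2L || trimws(lines[1]) != "OFF")
    parse_fail(path, 1L, "not an OFF file")
  cnt <- as.integer(strsplit(trimws(lines[2]), "\\s+")[[1]])
  nv <- cnt[1]; nf <- cnt[2]
  if (length(lines) < 2L + nv + nf) parse_fail(path, length(lines), "truncated body")
  V <- matrix(scan(text = lines[2L + seq_len(nv)], quiet = TRUE), nv, byrow = TRUE)[, 1:3, drop = FALSE]
  Fraw <- lapply(seq_len(nf), function(k) {
    tok <- as.integer(strsplit(trimws(lines[2L + nv + k]), "\\s+")[[1]])
    if (tok[1] != 3L) parse_fail(path, 2L + nv + k, "non-triangular face")
    tok[2:4] + 1L
  })
  trimesh(V, do.call(rbind, Fraw))
}

write_off <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("OFF", con)
  writeLines(sprintf("%d %d 0", nrow(mesh$vertices), nrow(mesh$faces)), con)
  writeLines(apply(mesh$vertices, 1, function(v)
    sprintf("%.17g %.17g %.17g", v[1], v[2], v[3])), con)
  writeLines(apply(mesh$faces - 1L, 1, function(f)
    sprintf("3 %d %d %d", f[1], f[2], f[3])), con)
}

# STL stores per-facet vertex triples (no shared connectivity); reading
# rebuilds connectivity by exact coordinate matching.
read_stl <- function(path) {
  sz <- file.size(path)
  if (sz < 15) parse_fail(path, 1L, "file too short for STL")
  head <- readBin(path, "raw", n = 5L)
  if (identical(rawToChar(head), "solid")) {
    tri <- read_stl_ascii(path)
  } else {
    tri <- read_stl_bin(path)
  }
  stl_to_mesh(tri)
}

read_stl_ascii <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vl <- grep("^\\s*vertex\\s", lines)
  if (length(vl) == 0L || length(vl) %% 3L != 0L)
    parse_fail(path, length(lines), "ASCII STL vertex count not a multiple of 3")
  coords <- t(vapply(lines[vl], function(l) {
    as.numeric(strsplit(trimws(l), "\\s+")[[1]][2:4])
  }, numeric(3)))
  rownames(coords) <- NULL
  coords
}

read_stl_bin <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  readBin(con, "raw", n = 80L)
  nf <- readBin(con, "integer", n = 1L, size = 4L, endian = "little")
  coords <- matrix(0, nf * 3L, 3L)
  for (k in seq_len(nf)) {
    vals <- readBin(con, "numeric", n = 12L, size = 4L, endian = "little")
    attrib <- readBin(con, "integer", n = 1L, size = 2L, endian = "little")
    if (length(vals) < 12L) parse_fail(path, k, "truncated binary STL record")
    coords[3L * k - 2L, ] <- vals[4:6]
    coords[3L * k - 1L, ] <- vals[7:9]
    coords[3L * k, ] <- vals[10:12]
  }
  coords
}

stl_to_mesh <- function(coords) {
  key <- apply(coords, 1, function(v) sprintf("%.9g|%.9g|%.9g", v[1], v[2], v[3]))
  uk <- !duplicated(key)
  V <- coords[uk, , drop = FALSE]
  idx <- match(key, key[uk])
  F <- matrix(idx, ncol = 3, byrow = TRUE)
  trimesh(V, F)
}

write_stl_ascii <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("solid trimesh", con)
  V <- mesh$vertices; F <- mesh$faces; N <- mesh$normal
  out <- character(nrow(F) * 7L)
  p <- 0L
  for (f in seq_len(nrow(F))) {
    out[p + 1L] <- sprintf("  facet normal %.9g %.9g %.9g", N[f, 1], N[f, 2], N[f, 3])
    out[p + 2L] <- "    outer loop"
    for (k in 1:3)
      out[p + 2L + k] <- sprintf("      vertex %.9g %.9g %.9g",
                                 V[F[f, k], 1], V[F[f, k], 2], V[F[f, k], 3])
    out[p + 6L] <- "    endloop"
    out[p + 7L] <- "  endfacet"
    p <- p + 7L
  }
  writeLines(out, con)
  writeLines("endsolid trimesh", con)
}

write_stl_bin <- function(mesh, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.raw(rep(0L, 80L)), con)
  writeBin(as.integer(nrow(mesh$faces)), con, size = 4L, endian = "little")
  V <- mesh$vertices; F <- mesh$faces; N <- mesh$normal
  for (f in seq_len(nrow(F))) {
    writeBin(as.numeric(c(N[f, ], V[F[f, 1], ], V[F[f, 2], ], V[F[f, 3], ])),
             con, size = 4L, endian = "little")
    writeBin(0L, con, size = 2L, endian = "little")
  }
}
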