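#' Read and write triangle meshes (OBJ, STL)
#'
#' Minimal readers/writers for the two interchange formats used for flesh
#' model segments.  OBJ support covers `v` and `f` records (polygonal
#' faces are fan-triangulated; texture/normal indices in `f` records are
#' ignored).  STL support covers both ASCII and binary files on read, and
#' ASCII on write.  Units are metres; no unit conversion is applied.
#'
#' @param path file path.
#' @param geometry a `mesh_geometry`.
#' @param validate validate the mesh after reading (closed, consistently
#'   oriented); set `FALSE` to load a mesh you intend to repair.
#' @return `read_obj()`/`read_stl()` return a `mesh_geometry`;
#'   the writers return `path` invisibly.
#' @export
read_obj <- function(path, validate = TRUE) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  vlines <- lines[startsWith(lines, "v ")]
  flines <- lines[startsWith(lines, "f ")]
  if (length(vlines) == 0 || length(flines) == 0) {
    rlang::abort("OBJ file contains no vertices or no faces.")
  }
  v <- do.call(rbind, lapply(strsplit(vlines, "\\s+"), function(x) {
    as.numeric(x[2:4])
  }))
  faces <- do.call(rbind, lapply(strsplit(flines, "\\s+"), function(x) {
    idx <- vapply(x[-1], function(tok) {
      as.integer(strsplit(tok, "/", fixed = TRUE)[[1]][1])
    }, integer(1))
    if (length(idx) < 3) rlang::abort("OBJ face with fewer than 3 vertices.")
    # fan triangulation for polygons
    k <- seq_len(length(idx) - 2)
    cbind(idx[1], idx[k + 1], idx[k + 2])
  }))
  mesh_geometry(v, faces, validate = validate)
}

#' @rdname read_obj
#' @export
write_obj <- function(geometry, path) {
  geometry <- as_mesh(geometry)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# paleohydro mesh", con)
  writeLines(sprintf(
    "v %.9g %.9g %.9g",
    geometry$vertices[, 1], geometry$vertices[, 2], geometry$vertices[, 3]
  ), con)
  writeLines(sprintf(
    "f %d %d %d",
    geometry$faces[, 1], geometry$faces[, 2], geometry$faces[, 3]
  ), con)
  invisible(path)
}

#' @rdname read_obj
#' @export
read_stl <- function(path, validate = TRUE) {
  head <- readBin(path, "raw", n = 5)
  tris <- if (identical(rawToChar(head), "solid") && is_ascii_stl(path)) {
    read_stl_ascii(path)
  } else {
    read_stl_binary(path)
  }
  # weld coincident vertices so the mesh is topologically closed
  key <- paste(tris[, 1], tris[, 2], tris[, 3])
  uniq <- !duplicated(key)
  idx <- match(key, key[uniq])
  v <- tris[uniq, , drop = FALSE]
  f <- matrix(idx, ncol = 3, byrow = TRUE)
  mesh_geometry(v, f, validate = validate)
}

is_ascii_stl <- function(path) {
  # binary STLs can also start with "solid"; check for a facet keyword
  txt <- readChar(path, nchars = min(file.size(path), 4000), useBytes = TRUE)
  grepl("facet", txt, fixed = TRUE)
}

read_stl_ascii <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  vlines <- lines[startsWith(lines, "vertex")]
  if (length(vlines) == 0 || length(vlines) %% 3 != 0) {
    rlang::abort("ASCII STL vertex records are missing or not in triples.")
  }
  do.call(rbind, lapply(strsplit(vlines, "\\s+"), function(x) {
    as.numeric(x[2:4])
  }))
}

read_stl_binary <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  readBin(con, "raw", n = 80)
  n <- readBin(con, "integer", n = 1, size = 4, endian = "little")
  tris <- matrix(0, 3 * n, 3)
  for (i in seq_len(n)) {
    vals <- readBin(con, "numeric", n = 12, size = 4, endian = "little")
    tris[3 * i - 2, ] <- vals[4:6]
    tris[3 * i - 1, ] <- vals[7:9]
    tris[3 * i, ] <- vals[10:12]
    readBin(con, "raw", n = 2)
  }
  tris
}

#' @rdname read_obj
#' @export
write_stl <- function(geometry, path) {
  geometry <- as_mesh(geometry)
  v <- geometry$vertices
  f <- geometry$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  c_ <- v[f[, 3], , drop = FALSE]
  u <- b - a
  w <- c_ - a
  nrm <- cbind(
    u[, 2] * w[, 3] - u[, 3] * w[, 2],
    u[, 3] * w[, 1] - u[, 1] * w[, 3],
    u[, 1] * w[, 2] - u[, 2] * w[, 1]
  )
  len <- sqrt(rowSums(nrm^2))
  nrm <- nrm / ifelse(len > 0, len, 1)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("solid paleohydro", con)
  block <- paste0(
    sprintf("facet normal %.9g %.9g %.9g\n", nrm[, 1], nrm[, 2], nrm[, 3]),
    "outer loop\n",
    sprintf("vertex %.9g %.9g %.9g\n", a[, 1], a[, 2], a[, 3]),
    sprintf("vertex %.9g %.9g %.9g\n", b[, 1], b[, 2], b[, 3]),
    sprintf("vertex %.9g %.9g %.9g\n", c_[, 1], c_[, 2], c_[, 3]),
    "endloop\nendfacet"
  )
  writeLines(block, con)
  writeLines("endsolid paleohydro", con)
  invisible(path)
}
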