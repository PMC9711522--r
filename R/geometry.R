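#' Segment geometries
#'
#' A flesh model is assembled from segments, each carrying a geometry.  A
#' geometry is either a closed triangle mesh ([mesh_geometry()]) or a
#' parametric solid with exact closed-form properties ([box_geometry()],
#' [frustum_geometry()], [ellipsoid_geometry()]).  All dimensions are in
#' metres, in a right-handed frame with +x anterior and +z up.
#'
#' @param vertices numeric matrix, one row per vertex, columns x/y/z (m).
#' @param faces integer matrix, one row per triangle, 1-based vertex
#'   indices, consistently oriented with outward normals.
#' @param validate check that the mesh is closed and consistently
#'   oriented (each directed edge used exactly once, with its reverse
#'   also present) and that total signed volume is positive.
#' @return An object of class `mesh_geometry` (also `segment_geometry`).
#' @examples
#' cube <- mesh_box(1, 1, 1)
#' mass_properties(cube, density = 1000)
#' @export
mesh_geometry <- function(vertices, faces, validate = TRUE) {
  vertices <- as.matrix(vertices)
  faces <- matrix(as.integer(as.matrix(faces)), ncol = 3)
  storage.mode(vertices) <- "double"
  if (ncol(vertices) != 3) {
    rlang::abort("`vertices` must have three columns (x, y, z in metres).")
  }
  g <- structure(
    list(vertices = vertices, faces = faces),
    class = c("mesh_geometry", "segment_geometry")
  )
  if (validate) validate_mesh(g)
  g
}

#' Validate that a triangle mesh is closed and consistently oriented
#'
#' Every directed edge must occur exactly once and its reverse must also
#' occur (so the surface is watertight with a consistent winding), and the
#' total signed volume must be positive (outward-facing normals).  The
#' error message names the offending edges, which is usually enough to
#' locate a hole or a flipped triangle.
#'
#' @param geometry a `mesh_geometry`.
#' @return `geometry`, invisibly, if valid; otherwise an error.
#' @export
validate_mesh <- function(geometry) {
  f <- geometry$faces
  v <- geometry$vertices
  if (anyNA(v) || anyNA(f)) rlang::abort("Mesh contains missing values.")
  if (min(f) < 1 || max(f) > nrow(v)) {
    rlang::abort("Face indices fall outside the vertex table.")
  }
  from <- c(f[, 1], f[, 2], f[, 3])
  to <- c(f[, 2], f[, 3], f[, 1])
  key <- paste(from, to)
  dup <- duplicated(key)
  if (any(dup)) {
    bad <- utils::head(unique(key[dup]), 5)
    rlang::abort(c(
      "Mesh is not consistently oriented: repeated directed edges.",
      stats::setNames(paste("edge", bad), rep("x", length(bad)))
    ))
  }
  rev_key <- paste(to, from)
  open <- !(key %in% rev_key)
  if (any(open)) {
    bad <- utils::head(key[open], 5)
    rlang::abort(c(
      "Mesh is open: directed edges without a reverse partner.",
      stats::setNames(paste("edge", bad), rep("x", length(bad)))
    ))
  }
  if (signed_mesh_volume(v, f) <= 0) {
    rlang::abort("Mesh has non-positive signed volume; normals appear inward.")
  }
  invisible(geometry)
}

# signed volume of a closed oriented mesh about the origin (m^3)
signed_mesh_volume <- function(v, f) {
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  c_ <- v[f[, 3], , drop = FALSE]
  sum(tet_signed_volumes(a, b, c_))
}

# per-face signed tetra volumes (origin, a, b, c)
tet_signed_volumes <- function(a, b, c_) {
  (a[, 1] * (b[, 2] * c_[, 3] - b[, 3] * c_[, 2]) +
    a[, 2] * (b[, 3] * c_[, 1] - b[, 1] * c_[, 3]) +
    a[, 3] * (b[, 1] * c_[, 2] - b[, 2] * c_[, 1])) / 6
}

mesh_surface_area <- function(v, f) {
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  c_ <- v[f[, 3], , drop = FALSE]
  u <- b - a
  w <- c_ - a
  cx <- u[, 2] * w[, 3] - u[, 3] * w[, 2]
  cy <- u[, 3] * w[, 1] - u[, 1] * w[, 3]
  cz <- u[, 1] * w[, 2] - u[, 2] * w[, 1]
  sum(sqrt(cx^2 + cy^2 + cz^2)) / 2
}

# volume and centroid of a closed oriented mesh (signed tetra about origin)
mesh_volume_centroid <- function(v, f) {
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  c_ <- v[f[, 3], , drop = FALSE]
  vol <- tet_signed_volumes(a, b, c_)
  total <- sum(vol)
  centroid <- colSums(vol * (a + b + c_)) / (4 * total)
  list(volume = total, centroid = centroid)
}

#' Box, frustum and ellipsoid parametric geometries
#'
#' Parametric solids with exact volume and centre of mass.  The frustum is
#' a truncated cone with its axis along +z, base (radius `r1`) at
#' `base + c(0, 0, 0)`; the ellipsoid has semi-axes `a`, `b`, `c` along
#' x, y, z.  Surface areas are exact for box and frustum (lateral surface
#' plus both end caps); the ellipsoid area uses the Thomsen approximation
#' (p = 1.6075, error below about 1.1%).
#'
#' @param lx,ly,lz box edge lengths (m).
#' @param r1,r2 frustum base and top radii (m), strictly positive.
#' @param h frustum height (m).
#' @param a,b,c ellipsoid semi-axes (m).
#' @param center geometric centre of box/ellipsoid (length-3, m).
#' @param base centre of the frustum base disk (length-3, m).
#' @return A `segment_geometry` object.
#' @examples
#' frustum_geometry(1, 0.5, 2)
#' @export
box_geometry <- function(lx, ly, lz, center = c(0, 0, 0)) {
  check_positive(c(lx = lx, ly = ly, lz = lz))
  structure(
    list(lx = lx, ly = ly, lz = lz, center = as.numeric(center)),
    class = c("box_geometry", "segment_geometry")
  )
}

#' @rdname box_geometry
#' @export
frustum_geometry <- function(r1, r2, h, base = c(0, 0, 0)) {
  check_positive(c(r1 = r1, r2 = r2, h = h))
  structure(
    list(r1 = r1, r2 = r2, h = h, base = as.numeric(base)),
    class = c("frustum_geometry", "segment_geometry")
  )
}

#' @rdname box_geometry
#' @export
ellipsoid_geometry <- function(a, b, c, center = c(0, 0, 0)) {
  check_positive(c(a = a, b = b, c = c))
  structure(
    list(a = a, b = b, c = c, center = as.numeric(center)),
    class = c("ellipsoid_geometry", "segment_geometry")
  )
}

check_positive <- function(x) {
  bad <- !is.finite(x) | x <= 0
  if (any(bad)) {
    rlang::abort(paste0(
      "Dimensions must be strictly positive: ",
      paste(names(x)[bad], collapse = ", "), "."
    ))
  }
  invisible(x)
}

# ---- closed-form properties (internal generics) ----

geometry_volume <- function(g) UseMethod("geometry_volume")
geometry_area <- function(g) UseMethod("geometry_area")
geometry_centroid <- function(g) UseMethod("geometry_centroid")

#' @export
geometry_volume.box_geometry <- function(g) g$lx * g$ly * g$lz
#' @export
geometry_area.box_geometry <- function(g) {
  2 * (g$lx * g$ly + g$ly * g$lz + g$lx * g$lz)
}
#' @export
geometry_centroid.box_geometry <- function(g) g$center

#' @export
geometry_volume.frustum_geometry <- function(g) {
  pi * g$h * (g$r1^2 + g$r1 * g$r2 + g$r2^2) / 3
}
#' @export
geometry_area.frustum_geometry <- function(g) {
  slant <- sqrt(g$h^2 + (g$r1 - g$r2)^2)
  pi * (g$r1 + g$r2) * slant + pi * g$r1^2 + pi * g$r2^2
}
#' @export
geometry_centroid.frustum_geometry <- function(g) {
  # height of centroid above the base disk
  zbar <- g$h * (g$r1^2 + 2 * g$r1 * g$r2 + 3 * g$r2^2) /
    (4 * (g$r1^2 + g$r1 * g$r2 + g$r2^2))
  g$base + c(0, 0, zbar)
}

#' @export
geometry_volume.ellipsoid_geometry <- function(g) 4 / 3 * pi * g$a * g$b * g$c
#' @export
geometry_area.ellipsoid_geometry <- function(g) {
  p <- 1.6075
  4 * pi * (((g$a * g$b)^p + (g$a * g$c)^p + (g$b * g$c)^p) / 3)^(1 / p)
}
#' @export
geometry_centroid.ellipsoid_geometry <- function(g) g$center

#' @export
geometry_volume.mesh_geometry <- function(g) {
  mesh_volume_centroid(g$vertices, g$faces)$volume
}
#' @export
geometry_area.mesh_geometry <- function(g) {
  mesh_surface_area(g$vertices, g$faces)
}
#' @export
geometry_centroid.mesh_geometry <- function(g) {
  mesh_volume_centroid(g$vertices, g$faces)$centroid
}

# ---- mesh primitives ----

#' Triangle-mesh primitives
#'
#' Generators for closed, consistently oriented triangle meshes used as
#' analytic test bodies and as the discretisation of parametric segments:
#' an axis-aligned box, an icosphere (subdivided icosahedron projected to
#' the sphere), a conical frustum, an ellipsoid (scaled icosphere), and a
#' prism extruded along x from an arbitrary simple cross-section polygon
#' in the y-z plane.
#'
#' @param lx,ly,lz box edge lengths (m).
#' @param center geometric centre (length-3, m).
#' @param radius sphere radius (m).
#' @param subdivisions icosphere subdivision level; level `k` gives
#'   `20 * 4^k` faces.
#' @param r1,r2,h frustum base/top radii and height (m).
#' @param base centre of the frustum base disk.
#' @param n number of points around the frustum circumference.
#' @param a,b,c ellipsoid semi-axes (m).
#' @param section two-column matrix of (y, z) cross-section vertices in
#'   counter-clockwise order (viewed from +x).
#' @param length prism extent along x (m).
#' @param x0 x-coordinate of the near face of the prism.
#' @return A `mesh_geometry`.
#' @examples
#' s <- mesh_icosphere(1, subdivisions = 3)
#' nrow(s$faces)
#' @export
mesh_box <- function(lx = 1, ly = 1, lz = 1, center = c(lx, ly, lz) / 2) {
  check_positive(c(lx = lx, ly = ly, lz = lz))
  hx <- lx / 2
  hy <- ly / 2
  hz <- lz / 2
  v <- rbind(
    c(-hx, -hy, -hz), c(hx, -hy, -hz), c(hx, hy, -hz), c(-hx, hy, -hz),
    c(-hx, -hy, hz), c(hx, -hy, hz), c(hx, hy, hz), c(-hx, hy, hz)
  )
  v <- sweep(v, 2, as.numeric(center), "+")
  f <- rbind(
    c(1, 3, 2), c(1, 4, 3), # bottom (z-)
    c(5, 6, 7), c(5, 7, 8), # top (z+)
    c(1, 2, 6), c(1, 6, 5), # y-
    c(2, 3, 7), c(2, 7, 6), # x+
    c(3, 4, 8), c(3, 8, 7), # y+
    c(4, 1, 5), c(4, 5, 8) # x-
  )
  mesh_geometry(v, f)
}

#' @rdname mesh_box
#' @export
mesh_icosphere <- function(radius = 1, subdivisions = 3, center = c(0, 0, 0)) {
  check_positive(c(radius = radius))
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1)
  )
  v <- v / sqrt(1 + phi^2)
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2)
  )
  for (i in seq_len(subdivisions)) {
    sub <- subdivide_mesh(v, f)
    v <- sub$vertices
    f <- sub$faces
    v <- v / sqrt(rowSums(v^2)) # project back onto the unit sphere
  }
  v <- sweep(v * radius, 2, as.numeric(center), "+")
  mesh_geometry(v, f)
}

# midpoint subdivision: each triangle -> 4, shared midpoints merged
subdivide_mesh <- function(v, f) {
  n <- nrow(v)
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  ekey <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  uniq <- !duplicated(ekey)
  idx <- match(ekey, ekey[uniq]) + n
  mid <- (v[e[uniq, 1], , drop = FALSE] + v[e[uniq, 2], , drop = FALSE]) / 2
  nf <- nrow(f)
  m12 <- idx[seq_len(nf)]
  m23 <- idx[nf + seq_len(nf)]
  m31 <- idx[2 * nf + seq_len(nf)]
  faces <- rbind(
    cbind(f[, 1], m12, m31),
    cbind(f[, 2], m23, m12),
    cbind(f[, 3], m31, m23),
    cbind(m12, m23, m31)
  )
  list(vertices = rbind(v, mid), faces = faces)
}

#' @rdname mesh_box
#' @export
mesh_frustum <- function(r1 = 1, r2 = 0.5, h = 1, base = c(0, 0, 0), n = 64) {
  check_positive(c(r1 = r1, r2 = r2, h = h))
  theta <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  ring1 <- cbind(r1 * cos(theta), r1 * sin(theta), 0)
  ring2 <- cbind(r2 * cos(theta), r2 * sin(theta), h)
  v <- rbind(ring1, ring2, c(0, 0, 0), c(0, 0, h))
  cb <- 2 * n + 1 # bottom centre
  ct <- 2 * n + 2 # top centre
  i <- seq_len(n)
  j <- c(seq_len(n)[-1], 1)
  side <- rbind(
    cbind(i, j, n + j),
    cbind(i, n + j, n + i)
  )
  bottom <- cbind(cb, j, i) # wind so normal points to z-
  top <- cbind(ct, n + i, n + j)
  v <- sweep(v, 2, as.numeric(base), "+")
  mesh_geometry(v, rbind(side, bottom, top))
}

#' @rdname mesh_box
#' @export
mesh_ellipsoid <- function(a = 1, b = 1, c = 1, center = c(0, 0, 0),
                           subdivisions = 3) {
  s <- mesh_icosphere(1, subdivisions = subdivisions)
  v <- s$vertices
  v[, 1] <- v[, 1] * a
  v[, 2] <- v[, 2] * b
  v[, 3] <- v[, 3] * c
  mesh_geometry(sweep(v, 2, as.numeric(center), "+"), s$faces)
}

#' @rdname mesh_box
#' @export
mesh_prism <- function(section, length = 1, x0 = 0) {
  section <- as.matrix(section)
  if (ncol(section) != 2 || nrow(section) < 3) {
    rlang::abort("`section` must be an n x 2 matrix of (y, z) points, n >= 3.")
  }
  n <- nrow(section)
  near <- cbind(x0, section[, 1], section[, 2])
  far <- cbind(x0 + length, section[, 1], section[, 2])
  cyz <- colMeans(section)
  v <- rbind(near, far, c(x0, cyz[1], cyz[2]), c(x0 + length, cyz[1], cyz[2]))
  cn <- 2 * n + 1
  cf <- 2 * n + 2
  i <- seq_len(n)
  j <- c(seq_len(n)[-1], 1)
  # section CCW viewed from +x; near cap normal -x, far cap +x
  near_cap <- cbind(cn, j, i)
  far_cap <- cbind(cf, n + i, n + j)
  side <- rbind(
    cbind(i, j, n + j),
    cbind(i, n + j, n + i)
  )
  mesh_geometry(v, rbind(near_cap, far_cap, side))
}

#' Convert a geometry to a triangle mesh
#'
#' Parametric geometries are discretised; meshes are returned unchanged.
#' The discretisation density is controlled by `n` (points around a
#' frustum) and `subdivisions` (icosphere level for ellipsoids).
#'
#' @param geometry a `segment_geometry`.
#' @param n,subdivisions discretisation controls.
#' @return A `mesh_geometry`.
#' @export
as_mesh <- function(geometry, n = 64, subdivisions = 4) {
  UseMethod("as_mesh")
}

#' @export
as_mesh.mesh_geometry <- function(geometry, n = 64, subdivisions = 4) geometry

#' @export
as_mesh.box_geometry <- function(geometry, n = 64, subdivisions = 4) {
  mesh_box(geometry$lx, geometry$ly, geometry$lz, center = geometry$center)
}

#' @export
as_mesh.frustum_geometry <- function(geometry, n = 64, subdivisions = 4) {
  mesh_frustum(geometry$r1, geometry$r2, geometry$h,
    base = geometry$base, n = n
  )
}

#' @export
as_mesh.ellipsoid_geometry <- function(geometry, n = 64, subdivisions = 4) {
  mesh_ellipsoid(geometry$a, geometry$b, geometry$c,
    center = geometry$center, subdivisions = subdivisions
  )
}

# ---- rigid transforms ----

#' Rigid transforms
#'
#' `rotation_x/y/z()` build 3x3 rotation matrices for a right-handed
#' rotation about the named axis; `transform_geometry()` applies a
#' rotation followed by a translation.  Parametric geometries accept pure
#' translations directly; a genuine rotation converts them to a mesh
#' first (their axis alignment is part of the closed form).
#'
#' @param angle_deg rotation angle in degrees.
#' @param geometry a `segment_geometry`.
#' @param rotation 3x3 rotation matrix.
#' @param translation length-3 translation (m).
#' @return `transform_geometry()` returns a `segment_geometry`.
#' @export
rotation_x <- function(angle_deg) {
  a <- angle_deg * pi / 180
  matrix(c(1, 0, 0, 0, cos(a), sin(a), 0, -sin(a), cos(a)), 3, 3)
}

#' @rdname rotation_x
#' @export
rotation_y <- function(angle_deg) {
  a <- angle_deg * pi / 180
  matrix(c(cos(a), 0, -sin(a), 0, 1, 0, sin(a), 0, cos(a)), 3, 3)
}

#' @rdname rotation_x
#' @export
rotation_z <- function(angle_deg) {
  a <- angle_deg * pi / 180
  matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
}

#' @rdname rotation_x
#' @export
transform_geometry <- function(geometry, rotation = diag(3),
                               translation = c(0, 0, 0)) {
  translation <- as.numeric(translation)
  is_identity <- isTRUE(all.equal(rotation, diag(3), tolerance = 1e-12))
  if (inherits(geometry, "mesh_geometry")) {
    v <- geometry$vertices %*% t(rotation)
    v <- sweep(v, 2, translation, "+")
    return(mesh_geometry(v, geometry$faces, validate = FALSE))
  }
  if (is_identity) {
    if (inherits(geometry, "frustum_geometry")) {
      geometry$base <- geometry$base + translation
    } else {
      geometry$center <- geometry$center + translation
    }
    return(geometry)
  }
  transform_geometry(as_mesh(geometry), rotation, translation)
}
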