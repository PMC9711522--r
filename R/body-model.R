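#' Body segments
#'
#' A named piece of a flesh model: a geometry, a tissue density and a
#' functional role.  Tissue densities must lie in (0, 2000] kg/m^3 (fat
#' ~900 up to compact bone ~2000); air-space segments have density 0 and
#' role `"air"` — they contribute displaced volume but no mass.
#'
#' @param name segment name.
#' @param geometry a `segment_geometry`.
#' @param density tissue density in kg/m^3 (0 for air spaces).
#' @param role one of `"axial head-trunk"`, `"axial tail"`, `"sail"`,
#'   `"forelimb"`, `"hindlimb"`, `"air"`.
#' @return A `body_segment`.
#' @examples
#' body_segment("trunk", ellipsoid_geometry(2, 0.6, 0.6), 850, "axial head-trunk")
#' @export
body_segment <- function(name, geometry, density,
                         role = c(
                           "axial head-trunk", "axial tail", "sail",
                           "forelimb", "hindlimb", "air"
                         )) {
  role <- match.arg(role)
  if (!inherits(geometry, "segment_geometry")) {
    rlang::abort("`geometry` must be a segment_geometry.")
  }
  if (role == "air") {
    if (density != 0) rlang::abort("Air-space segments must have density 0.")
  } else if (!is.finite(density) || density <= 0 || density > 2000) {
    rlang::abort("Tissue density must lie in (0, 2000] kg/m^3.")
  }
  structure(
    list(name = name, geometry = geometry, density = density, role = role),
    class = "body_segment"
  )
}

#' Flesh models
#'
#' An ordered collection of density-tagged body segments with a posture
#' label.  `assemble_model()` builds the model and returns it together
#' with its aggregate mass properties; segment overlap is not detected
#' (segments are expected to tile the body).
#'
#' @param segments a list of [body_segment()]s, at least one non-air.
#' @param posture posture label.
#' @param air_fraction optional bulk air fraction applied via
#'   [apply_air_fraction()] after assembly.
#' @return `flesh_model()` returns a `flesh_model`; `assemble_model()`
#'   returns a list with elements `model` and `properties` (a tibble with
#'   one row per segment plus a `whole body` row).
#' @examples
#' segs <- list(
#'   body_segment("lower", box_geometry(1, 1, 1, center = c(0, 0, 0.5)), 1000,
#'     role = "axial head-trunk"
#'   ),
#'   body_segment("upper", box_geometry(1, 1, 1, center = c(0, 0, 1.5)), 500,
#'     role = "axial head-trunk"
#'   )
#' )
#' assemble_model(segs)$properties
#' @export
flesh_model <- function(segments,
                        posture = c(
                          "bipedal", "hybrid swim", "axial swim",
                          "wading strike"
                        ),
                        air_fraction = NULL) {
  posture <- match.arg(posture)
  if (length(segments) == 0) {
    rlang::abort("A flesh model needs at least one segment.")
  }
  if (!all(purrr::map_lgl(segments, inherits, "body_segment"))) {
    rlang::abort("All elements of `segments` must be body_segments.")
  }
  if (!any(purrr::map_lgl(segments, ~ .x$role != "air"))) {
    rlang::abort("A flesh model needs at least one non-air segment.")
  }
  model <- structure(
    list(segments = segments, posture = posture, air_fraction = NA_real_),
    class = "flesh_model"
  )
  if (!is.null(air_fraction)) model <- apply_air_fraction(model, air_fraction)
  model
}

#' @rdname flesh_model
#' @export
assemble_model <- function(segments, posture = "bipedal", air_fraction = NULL) {
  model <- flesh_model(segments, posture = posture, air_fraction = air_fraction)
  list(model = model, properties = mass_properties(model, by_part = TRUE))
}

#' Mass properties
#'
#' Volume, external surface area, mass, mean density and centre of mass.
#' Mesh geometries use exact signed-tetrahedron summation about the
#' origin; parametric geometries use closed forms.  For a flesh model the
#' aggregate mass is the exact sum of segment masses and the aggregate CM
#' is the mass-weighted mean of segment CMs; air segments contribute
#' volume but no mass.  A bulk air fraction `f` (set by
#' [apply_air_fraction()]) rescales mass by `(1 - f)` without moving the
#' CM (the airless tissue density is scaled uniformly).
#'
#' @param x a `segment_geometry`, `body_segment`, `flesh_model` or
#'   preset model.
#' @param density tissue density (kg/m^3) when `x` is a bare geometry.
#' @param by_part for models: return one row per segment plus a
#'   `whole body` row instead of the aggregate row only.
#' @param ... passed on between methods.
#' @return A tibble with columns `part`, `volume` (m^3), `area` (m^2),
#'   `mass` (kg), `density` (kg/m^3), `cm_x`, `cm_y`, `cm_z` (m).
#' @examples
#' mass_properties(mesh_box(1, 1, 1), density = 1000)
#' @export
mass_properties <- function(x, ...) UseMethod("mass_properties")

#' @rdname mass_properties
#' @export
mass_properties.segment_geometry <- function(x, density = 1000, ...) {
  if (!is.finite(density) || density < 0) {
    rlang::abort("`density` must be non-negative.")
  }
  v <- geometry_volume(x)
  if (!is.finite(v) || v <= 0) {
    rlang::abort("Geometry has non-positive volume.")
  }
  cm <- unname(geometry_centroid(x))
  tibble::tibble(
    part = class(x)[1],
    volume = unname(v),
    area = unname(geometry_area(x)),
    mass = unname(density * v),
    density = density,
    cm_x = cm[1], cm_y = cm[2], cm_z = cm[3]
  )
}

#' @rdname mass_properties
#' @export
mass_properties.body_segment <- function(x, ...) {
  out <- mass_properties(x$geometry, density = x$density)
  out$part <- x$name
  out
}

#' @rdname mass_properties
#' @export
mass_properties.flesh_model <- function(x, by_part = FALSE, ...) {
  parts <- purrr::map(x$segments, mass_properties)
  parts <- dplyr::bind_rows(parts)
  tissue <- purrr::map_lgl(x$segments, ~ .x$role != "air")
  f0 <- implied_air_fraction(parts, tissue)
  f <- if (is.na(x$air_fraction)) f0 else x$air_fraction
  # a bulk air fraction rescales every tissue mass uniformly; the default
  # is whatever the explicit air-space segments already imply
  parts$mass[tissue] <- parts$mass[tissue] * (1 - f) / (1 - f0)
  parts$density <- ifelse(parts$volume > 0, parts$mass / parts$volume, 0)
  whole <- aggregate_properties(parts)
  if (by_part) dplyr::bind_rows(parts, whole) else whole
}

# air volume already present as explicit segments, as a fraction of total
implied_air_fraction <- function(parts, tissue) {
  v_air <- sum(parts$volume[!tissue])
  v_tot <- sum(parts$volume)
  if (v_tot <= 0) 0 else v_air / v_tot
}

aggregate_properties <- function(parts) {
  v <- sum(parts$volume)
  m <- sum(parts$mass)
  cm <- if (m > 0) {
    c(
      sum(parts$mass * parts$cm_x),
      sum(parts$mass * parts$cm_y),
      sum(parts$mass * parts$cm_z)
    ) / m
  } else {
    c(NA_real_, NA_real_, NA_real_)
  }
  tibble::tibble(
    part = "whole body",
    volume = v,
    area = sum(parts$area),
    mass = m,
    density = m / v,
    cm_x = cm[1], cm_y = cm[2], cm_z = cm[3]
  )
}

#' Apply a bulk internal air fraction
#'
#' Sets the whole-body air fraction `f` (of total body volume).  The
#' resulting mean density is `rho_tissue * (1 - f)`, where `rho_tissue`
#' is the airless mean density, and mass rescales accordingly; the CM is
#' recomputed with air spaces massless.  For segment models without
#' explicitly positioned air geometry the CM does not move (tissue mass
#' scales uniformly).
#'
#' @param model a `flesh_model` or preset model.
#' @param f air fraction of whole-body volume, in `[0, 1)`.
#' @return The model with the air fraction applied.
#' @examples
#' m <- flesh_model(list(body_segment("b", box_geometry(1, 1, 1), 952,
#'   role = "axial head-trunk"
#' )))
#' mass_properties(apply_air_fraction(m, 0.125))$density # 833
#' @export
apply_air_fraction <- function(model, f) {
  UseMethod("apply_air_fraction")
}

#' @export
apply_air_fraction.flesh_model <- function(model, f) {
  if (!is.finite(f) || f < 0 || f >= 1) {
    rlang::abort("Air fraction must lie in [0, 1).")
  }
  model$air_fraction <- f
  model
}

#' Report the centre of mass in the field convention
#'
#' Pure affine re-expression: horizontal distance anterior (+x) to the
#' apex of the acetabulum, and height above the ground plane, both in cm.
#'
#' @param props a mass-properties tibble (uses its first row) or a
#'   length-3 CM position in metres.
#' @param frame a [reference_frame()].
#' @return A tibble with `x_cm` (cm anterior to the acetabulum apex) and
#'   `y_cm` (cm above ground).
#' @examples
#' report_cm(c(0.153, 0, 2.40), reference_frame(c(0, 0, 2.4), ground = 0))
#' @export
report_cm <- function(props, frame) {
  if (is.null(frame)) rlang::abort("A reference frame is required.")
  cm <- if (is.numeric(props)) {
    props
  } else {
    c(props$cm_x[1], props$cm_y[1], props$cm_z[1])
  }
  tibble::tibble(
    x_cm = (cm[1] - frame$acetabulum[1]) * 100,
    y_cm = (cm[3] - frame$ground) * 100
  )
}

#' @param acetabulum position of the acetabulum apex (length-3, m).
#' @param ground ground-plane height (m); must sit below the body.
#' @rdname report_cm
#' @export
reference_frame <- function(acetabulum, ground = 0) {
  structure(
    list(acetabulum = as.numeric(acetabulum), ground = ground),
    class = "reference_frame"
  )
}
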