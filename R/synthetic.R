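#' Synthetic frustum-chain body with analytic ground truth
#'
#' Builds a head-neck-trunk-tail chain of parametric segments (frustums
#' and an ellipsoid trunk) along +x with per-segment tissue densities,
#' and returns both the flesh model and its exact closed-form mass
#' properties, computed here independently of the package's
#' mass-property code so the pair can serve as an oracle for the mesh
#' pipeline.  Deterministic given `seed` (the seed only jitters segment
#' proportions).
#'
#' @param n_tail number of tail frustum segments (>= 1).
#' @param scale overall length scale (m).
#' @param seed optional integer seed for proportion jitter.
#' @return A list with `model` (a `flesh_model`) and `truth` (a tibble
#'   of exact per-part and whole-body volume, mass and CM).
#' @examples
#' gen <- generate_frustum_body(seed = 1)
#' gen$truth[gen$truth$part == "whole body", ]
#' @export
generate_frustum_body <- function(n_tail = 3, scale = 1, seed = NULL) {
  if (n_tail < 1) rlang::abort("At least one tail segment is required.")
  check_positive(c(scale = scale))
  jitter <- if (is.null(seed)) {
    rep(1, 3 + n_tail)
  } else {
    withr::with_seed(seed, stats::runif(3 + n_tail, 0.9, 1.1))
  }
  # frustums run along +z; rotate each to lie along +x at assembly
  specs <- list(
    list(name = "head", r1 = 0.18 * scale, r2 = 0.10 * scale, h = 0.5 * scale, rho = 950, role = "axial head-trunk"),
    list(name = "neck", r1 = 0.25 * scale, r2 = 0.18 * scale, h = 0.7 * scale, rho = 900, role = "axial head-trunk"),
    list(name = "trunk", a = 0.9 * scale, b = 0.45 * scale, c = 0.55 * scale, rho = 850, role = "axial head-trunk")
  )
  r_base <- 0.40 * scale
  for (i in seq_len(n_tail)) {
    specs[[3 + i]] <- list(
      name = paste0("tail", i),
      r1 = r_base * (1 - (i - 1) / (n_tail + 1)),
      r2 = r_base * (1 - i / (n_tail + 1)),
      h = 0.8 * scale, rho = 1000, role = "axial tail"
    )
  }
  x0 <- 0
  segments <- list()
  truth_rows <- list()
  for (i in seq_along(specs)) {
    s <- specs[[i]]
    if (!is.null(s$h)) s$h <- s$h * jitter[i]
    if (is.null(s$a)) {
      # frustum along +x: base disk at x = x0 + h (anterior), so build
      # along +z and rotate -90 deg about y
      geom <- transform_geometry(
        as_mesh(frustum_geometry(s$r1, s$r2, s$h), n = 256),
        rotation = rotation_y(90),
        translation = c(x0 + 0, 0, 0)
      )
      vol <- pi * s$h * (s$r1^2 + s$r1 * s$r2 + s$r2^2) / 3
      zbar <- s$h * (s$r1^2 + 2 * s$r1 * s$r2 + 3 * s$r2^2) /
        (4 * (s$r1^2 + s$r1 * s$r2 + s$r2^2))
      cm <- c(x0 + zbar, 0, 0)
      x_next <- x0 + s$h
    } else {
      a <- s$a * jitter[i]
      geom <- ellipsoid_geometry(a, s$b, s$c, center = c(x0 + a, 0, 0))
      vol <- 4 / 3 * pi * a * s$b * s$c
      cm <- c(x0 + a, 0, 0)
      x_next <- x0 + 2 * a
    }
    segments[[i]] <- body_segment(s$name, geom, s$rho, s$role)
    truth_rows[[i]] <- tibble::tibble(
      part = s$name, volume = vol, mass = s$rho * vol,
      cm_x = cm[1], cm_y = cm[2], cm_z = cm[3]
    )
    x0 <- x_next
  }
  truth <- dplyr::bind_rows(truth_rows)
  whole <- tibble::tibble(
    part = "whole body",
    volume = sum(truth$volume),
    mass = sum(truth$mass),
    cm_x = sum(truth$mass * truth$cm_x) / sum(truth$mass),
    cm_y = 0, cm_z = 0
  )
  list(
    model = flesh_model(segments, posture = "axial swim"),
    truth = dplyr::bind_rows(truth, whole)
  )
}

#' Synthetic sail-backed stability test body
#'
#' An elliptical-section hull extruded along x, taller than wide, with a
#' thin low-density dorsal sail.  The deep section and the light sail
#' raise the upright centre of mass toward the centre of buoyancy and
#' leave only a narrow waterplane when floating, so the upright pose is
#' rotationally unstable while a side pose is stable — the qualitative
#' pattern expected of a deep-bodied, sail-backed floater.  With
#' `sail_height = 0` and equal hull semi-axes the body is rotationally
#' symmetric and the righting torque vanishes everywhere.
#'
#' @param hull_b,hull_c hull cross-section semi-axes (m): lateral (y) and
#'   vertical (z).
#' @param hull_length hull extent along x (m).
#' @param hull_density hull tissue density (kg/m^3).
#' @param sail_height,sail_thickness sail extent above the hull and
#'   lateral thickness (m); `sail_height = 0` omits the sail.
#' @param sail_density sail tissue density (kg/m^3).
#' @param n_section points around the hull cross-section.
#' @param mirror flip the sail to the ventral side (for symmetry checks).
#' @return A `flesh_model`.
#' @examples
#' body <- generate_sailback_body()
#' mass_properties(body)
#' @export
generate_sailback_body <- function(hull_b = 0.5, hull_c = 0.9,
                                   hull_length = 4, hull_density = 960,
                                   sail_height = 1.2, sail_thickness = 0.08,
                                   sail_density = 300, n_section = 48,
                                   mirror = FALSE) {
  check_positive(c(
    hull_b = hull_b, hull_c = hull_c, hull_length = hull_length,
    hull_density = hull_density
  ))
  if (sail_height < 0) rlang::abort("Sail height must be non-negative.")
  theta <- seq(0, 2 * pi, length.out = n_section + 1)[-(n_section + 1)]
  section <- cbind(hull_b * cos(theta), hull_c * sin(theta))
  hull <- mesh_prism(section, length = hull_length, x0 = 0)
  segments <- list(
    body_segment("hull", hull, hull_density, "axial head-trunk")
  )
  if (sail_height > 0) {
    zc <- if (mirror) -(hull_c + sail_height / 2) else hull_c + sail_height / 2
    sail <- box_geometry(
      hull_length, sail_thickness, sail_height,
      center = c(hull_length / 2, 0, zc)
    )
    segments[[2]] <- body_segment("sail", sail, sail_density, "sail")
  }
  flesh_model(segments, posture = "axial swim")
}

#' Synthetic area-allometry series
#'
#' Area pairs following `part = 10^intercept * total^slope * 10^eps`
#' with `eps ~ Normal(0, noise_sd)` (lognormal noise, matching the
#' log-log fitting model); total areas are log-uniform over
#' `total_range`.  Emulates a crocodylian growth series of paddle/tail
#' areas against total body area.  Bit-for-bit deterministic under
#' `seed`.
#'
#' @param n number of specimens (>= 3).
#' @param slope,intercept generating power law (log10 scale intercept).
#' @param noise_sd standard deviation of the log10 noise.
#' @param seed integer seed.
#' @param total_range range of total areas (m^2), sampled log-uniformly.
#' @param part_label label for the part column.
#' @return A tibble with `specimen`, `part_area`, `total_area`,
#'   `part_label`.
#' @examples
#' generate_allometry_series(n = 5, slope = 1, seed = 42)
#' @export
generate_allometry_series <- function(n = 30, slope = 1.0,
                                      intercept = -1.0, noise_sd = 0.05,
                                      seed = NULL,
                                      total_range = c(0.05, 60),
                                      part_label = "hind-foot paddle") {
  if (n < 3) rlang::abort("At least 3 specimens are required.")
  if (noise_sd < 0) rlang::abort("`noise_sd` must be non-negative.")
  gen <- function() {
    lt <- stats::runif(n, log10(total_range[1]), log10(total_range[2]))
    eps <- stats::rnorm(n, 0, noise_sd)
    tibble::tibble(
      specimen = sprintf("s%02d", seq_len(n)),
      part_area = 10^(intercept + slope * lt + eps),
      total_area = 10^lt,
      part_label = part_label
    )
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

#' Synthetic caudal centrum series
#'
#' Centrum length/height series along the tail under one of three
#' elongation-ratio profiles: `"uniform"` (ratio ~1 throughout, the
#' Spinosaurus subquadrate pattern), `"distally-elongating"` (ratio
#' rising toward the tail tip, the crocodylian/varanid spool trend), or
#' `"disc"` (ratio falling distally, the derived mosasaur pattern).
#' Heights taper distally; multiplicative lognormal noise; deterministic
#' under `seed`.
#'
#' @param profile profile label.
#' @param n number of caudal positions (>= 5).
#' @param noise_sd standard deviation of the log10 multiplicative noise.
#' @param seed integer seed.
#' @param taxon taxon label for the output.
#' @return A tibble with `taxon`, `position`, `centrum_length`,
#'   `centrum_height`.
#' @examples
#' generate_centrum_series("disc", n = 10, seed = 7)
#' @export
generate_centrum_series <- function(profile = c(
                                      "uniform",
                                      "distally-elongating", "disc"
                                    ),
                                    n = 20, noise_sd = 0, seed = NULL,
                                    taxon = NULL) {
  profile <- tryCatch(match.arg(profile), error = function(e) {
    rlang::abort(sprintf("Unknown centrum profile label '%s'.", profile[1]))
  })
  if (n < 5) rlang::abort("At least 5 caudal positions are required.")
  if (noise_sd < 0) rlang::abort("`noise_sd` must be non-negative.")
  taxon <- taxon %||% paste0("synthetic-", profile)
  gen <- function() {
    t <- seq(0, 1, length.out = n)
    ratio <- switch(profile,
      "uniform" = rep(1.05, n),
      "distally-elongating" = 1.0 + 1.0 * t,
      "disc" = 1.2 - 0.7 * t
    )
    height <- 60 * exp(-1.5 * t) # mm, tapering distally
    noise <- 10^stats::rnorm(n, 0, noise_sd)
    tibble::tibble(
      taxon = taxon,
      position = seq_len(n),
      centrum_length = ratio * height * noise,
      centrum_height = height
    )
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}
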