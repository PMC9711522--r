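#' Published constants for the adult Spinosaurus aegyptiacus flesh model
#'
#' The literature summary constants for the CT-derived adult flesh model:
#' whole-body volume 8.94 m^3, surface area 54.06 m^2, mean density 833
#' kg/m^3 and mass 7390 kg (avian-style, maximum air space); per-part
#' densities, volumes and surface areas; functional dimensions (total
#' length 13.53 m, tail length 6.61 m, tail depths 1.38/0.97/0.87 m); the
#' three internal air-space options with their densities, masses and CM
#' x-coordinates; and the swimming constants (thrust-power quadratic,
#' drag coefficient 0.0035, Reynolds number 752,400 at 1 m/s, alligator
#' tail kinematics).  These are stored reference values, returned
#' verbatim and never recomputed — the original mesh is not an input.
#' Note that the source tables are internally inexact: the printed part
#' masses sum to 6933 kg, not 7390, and 833 x 8.94 = 7447; the preset
#' preserves the printed values without reconciling them.
#'
#' @return A list of tibbles and named constants; see examples.
#' @examples
#' p <- spinosaurus_preset()
#' p$whole_body
#' p$air_options
#' @export
spinosaurus_preset <- function() {
  list(
    whole_body = tibble::tibble(
      part = "whole body",
      volume = 8.94, area = 54.06, mass = 7390, density = 833,
      cm_x = NA_real_, cm_y = NA_real_, cm_z = NA_real_
    ),
    densities = tibble::tibble(
      part = c(
        "whole body", "axial body (excluding lung/sail)",
        "axial head-trunk", "axial tail", "forelimb (paired)",
        "hind limb (paired)", "dorsocaudal sail", "lungs"
      ),
      density = c(833, 788, 850, 1000, 1050, 1050, 1196, 0),
      pct_axial_volume = c(NA, 100, 64.8, 35.2, 3.8, 11.1, 8.5, 12.5),
      mass = c(7390, 5794, 3209, 2585, 108, 590, 441, 0)
    ),
    dimensions = tibble::tibble(
      dimension = c(
        "total body length", "body length minus tail", "head length",
        "neck length", "trunk depth", "trunk sail depth",
        "trunk sail length", "tail length", "tail depth at base",
        "tail depth at midpoint", "tail depth at distal end",
        "tail depth average", "forelimb length", "hind limb length"
      ),
      metres = c(
        13.53, 6.92, 1.57, 2.18, 1.28, 1.93, 3.53, 6.61,
        1.38, 0.97, 0.87, 1.08, 1.85, 2.88
      )
    ),
    parts = tibble::tibble(
      part = c(
        "whole body", "body above waterline (floating)",
        "body below waterline (floating)", "head", "neck", "trunk",
        "trunk sail", "forelimb (both)", "hind limb (both)", "tail",
        "tail with axial muscle", "tail sail only",
        "airspace-minimum", "airspace-medium", "airspace-maximum"
      ),
      volume = c(
        8.94, 1.65, 7.27, 0.21, 0.78, 4.01, 0.40, 0.24, 0.45,
        2.81, 2.71, 0.10, 0.37, 0.67, 1.08
      ),
      area = c(
        54.06, 22.58, 31.38, 2.23, 4.37, 11.44, 10.06, 3.86, 5.29,
        16.56, 13.27, 3.17, 4.86, 6.63, 8.66
      )
    ),
    air_options = tibble::tibble(
      option = c("minimum", "medium", "maximum"),
      analog = c("lizard-like", "croc-like", "bird-like"),
      fraction = c(0.04, 0.08, 0.125),
      density = c(909, 875, 833),
      mass = c(8013, 7716, 7390),
      cm_x_cm = c(28.5, 23.2, 15.3)
    ),
    cm_report = tibble::tibble(x_cm = 15.3, y_cm = 240),
    water = list(rho_fresh = 1000, rho_salt = 1026, g = 9.8, nu = 1.0e-6),
    thrust = list(
      c0 = -164.93, c1 = 1899.1, c2 = -896.35,
      max_power_w = 820, max_force_n = 683, u_at_max = 1.2
    ),
    drag = list(cd = 0.0035, reynolds = 752400, reynolds_speed = 1.0,
      kappa_range = c(3, 5)
    ),
    kinematics = list(
      body_length = 13.53, amplitude_rel = 0.24, wavelength_rel = 0.57,
      frequency_hz = 0.25, tail_span = 0.87
    )
  )
}

#' Preset-backed flesh model interface
#'
#' Wraps the published constants behind the same interface as a segment
#' model, so downstream hydrostatic arithmetic can run on them.
#' `mass_properties()` on a preset model returns the printed values
#' verbatim for the selected air option; [apply_air_fraction()] computes
#' the mean density from the airless tissue density calibrated on the
#' maximum-air row (833 / 0.875 = 952 kg/m^3), which reproduces the
#' printed minimum/medium rows to within 1%.
#'
#' @param air air-space option: `"minimum"`, `"medium"` or `"maximum"`.
#' @return A `preset_model`.
#' @examples
#' mass_properties(preset_model("maximum"))
#' @export
preset_model <- function(air = c("maximum", "medium", "minimum")) {
  air <- match.arg(air)
  structure(
    list(preset = spinosaurus_preset(), air = air, air_fraction = NA_real_),
    class = "preset_model"
  )
}

# airless tissue density implied by the maximum-air row
preset_tissue_density <- function(preset) {
  opt <- preset$air_options
  opt$density[opt$option == "maximum"] / (1 - opt$fraction[opt$option == "maximum"])
}

#' @rdname mass_properties
#' @export
mass_properties.preset_model <- function(x, by_part = FALSE, ...) {
  p <- x$preset
  opt <- p$air_options[p$air_options$option == x$air, ]
  whole <- p$whole_body
  if (is.na(x$air_fraction)) {
    whole$density <- opt$density
    whole$mass <- opt$mass
    whole$cm_x <- opt$cm_x_cm / 100 # anterior to acetabulum apex, in m
  } else {
    rho <- preset_tissue_density(p) * (1 - x$air_fraction)
    whole$density <- rho
    whole$mass <- rho * whole$volume
  }
  if (!by_part) {
    return(whole)
  }
  parts <- dplyr::mutate(p$parts,
    mass = NA_real_, density = NA_real_,
    cm_x = NA_real_, cm_y = NA_real_, cm_z = NA_real_
  )
  dplyr::bind_rows(parts[parts$part != "whole body", ], whole)
}

#' @export
apply_air_fraction.preset_model <- function(model, f) {
  if (!is.finite(f) || f < 0 || f >= 1) {
    rlang::abort("Air fraction must lie in [0, 1).")
  }
  model$air_fraction <- f
  model
}

#' Write mass properties to CSV or JSON
#'
#' One row per part plus the whole-body row, mirroring the standard
#' volume/area/density/mass accounting layout.
#'
#' @param properties a mass-properties tibble.
#' @param path output path; format chosen by extension (`.csv`/`.json`).
#' @return `path`, invisibly.
#' @export
write_mass_properties <- function(properties, path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(properties, path,
      dataframe = "rows", digits = NA, pretty = TRUE
    )
  } else {
    utils::write.csv(properties, path, row.names = FALSE)
  }
  invisible(path)
}

#' Read a body-model configuration from YAML
#'
#' The config lists segments (name, kind, dimensions, optional
#' centre/base, density, role) plus an optional air option, either a
#' label (`minimum`/`medium`/`maximum`, resolved through the published
#' air-option table) or a numeric fraction.  Mesh segments reference an
#' OBJ or STL file path, resolved relative to the config file.
#'
#' @param path path to a YAML file.
#' @return A `flesh_model`.
#' @export
read_body_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$segments)) rlang::abort("Config has no `segments` list.")
  dir <- dirname(path)
  segments <- purrr::map(cfg$segments, function(s) {
    geom <- switch(s$kind,
      box = box_geometry(s$lx, s$ly, s$lz,
        center = s$center %||% c(0, 0, 0)
      ),
      frustum = frustum_geometry(s$r1, s$r2, s$h,
        base = s$base %||% c(0, 0, 0)
      ),
      ellipsoid = ellipsoid_geometry(s$a, s$b, s$c,
        center = s$center %||% c(0, 0, 0)
      ),
      mesh = {
        f <- file.path(dir, s$file)
        if (grepl("\\.obj$", s$file, ignore.case = TRUE)) {
          read_obj(f)
        } else {
          read_stl(f)
        }
      },
      rlang::abort(sprintf("Unknown segment kind '%s'.", s$kind))
    )
    body_segment(s$name, geom, s$density %||% 1000, s$role %||% "axial head-trunk")
  })
  air <- cfg$air %||% NA
  f <- if (is.character(air)) {
    opts <- spinosaurus_preset()$air_options
    if (!air %in% opts$option) {
      rlang::abort(sprintf("Unknown air option label '%s'.", air))
    }
    opts$fraction[opts$option == air]
  } else if (is.numeric(air)) {
    air
  } else {
    NULL
  }
  flesh_model(segments, posture = cfg$posture %||% "bipedal", air_fraction = f)
}
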