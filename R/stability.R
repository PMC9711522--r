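#' Righting-moment (roll stability) curve
#'
#' Rolls the body about its longitudinal (x) axis through the centre of
#' mass and computes, at each angle, the hydrostatic torque about that
#' axis.  In the `"floating"` formulation the waterline is re-solved at
#' every angle (Archimedes to 1e-6 relative) and the buoyant force is the
#' weight of the displaced water; in the `"submerged"` formulation the
#' body is fully immersed and the CB is the whole-volume centroid.  The
#' torque is the component in the +theta direction,
#' `tau = rho_w * V_sub * g * (y_CB - y_CM)`, so an equilibrium is stable
#' where `tau` crosses zero with negative slope (`tau = -dE/dtheta` for
#' the potential energy `E`).
#'
#' @param model a `flesh_model` (or bare `segment_geometry` with `mass`).
#' @param angles roll angles in degrees (0 = upright).
#' @param water a [water_model()] or density in kg/m^3.
#' @param mode `"floating"` or `"submerged"`.
#' @param mass body mass (kg); defaults to the model's own mass.
#' @param cm centre of mass (length 3, m); defaults to the model's own.
#' @return A `stability_curve` tibble: `angle` (deg), `torque` (N m),
#'   `v_sub`, `cm_y`, `cm_z`, `cb_y`, `cb_z`, `energy` (J, potential
#'   energy relative to the waterline, for the floating mode).
#' @examples
#' sphere <- flesh_model(list(body_segment(
#'   "s", ellipsoid_geometry(0.5, 0.5, 0.5), 800, "axial head-trunk"
#' )))
#' curve <- righting_moment_curve(sphere, angles = seq(0, 330, by = 30))
#' classify_equilibria(curve)
#' @export
righting_moment_curve <- function(model, angles = seq(0, 355, by = 5),
                                  water = "fresh",
                                  mode = c("floating", "submerged"),
                                  mass = NULL, cm = NULL) {
  mode <- match.arg(mode)
  wm <- if (is.list(water)) water else water_model(water)
  if (is.null(mass) || is.null(cm)) {
    if (!inherits(model, "flesh_model")) {
      rlang::abort("`mass` and `cm` are required for a bare geometry.")
    }
    props <- mass_properties(model)
    mass <- mass %||% props$mass
    cm <- cm %||% c(props$cm_x, props$cm_y, props$cm_z)
  }
  meshes <- displacement_meshes(model)
  rows <- purrr::map(angles, function(th) {
    rot <- rotation_x(th)
    rmesh <- purrr::map(meshes, function(m) {
      v <- sweep(m$vertices, 2, cm, "-") %*% t(rot)
      mesh_geometry(sweep(v, 2, cm, "+"), m$faces, validate = FALSE)
    })
    cm_r <- cm # rotation is about the CM itself
    if (mode == "floating") {
      fs <- solve_waterline_meshes(rmesh, mass, wm)
      v_sub <- fs$v_sub
      cb <- c(fs$cb_x, fs$cb_y, fs$cb_z)
      wl <- fs$waterline
    } else {
      acc_v <- 0
      acc_m <- c(0, 0, 0)
      for (m in rmesh) {
        mc <- mesh_volume_centroid(m$vertices, m$faces)
        acc_v <- acc_v + mc$volume
        acc_m <- acc_m + mc$volume * mc$centroid
      }
      v_sub <- acc_v
      cb <- acc_m / acc_v
      wl <- NA_real_
    }
    torque <- wm$rho * v_sub * wm$g * (cb[2] - cm_r[2])
    energy <- if (mode == "floating") {
      wm$g * (mass * (cm_r[3] - wl) - wm$rho * v_sub * (cb[3] - wl))
    } else {
      wm$g * (mass * cm_r[3] - wm$rho * v_sub * cb[3])
    }
    tibble::tibble(
      angle = th, torque = torque, v_sub = v_sub,
      cm_y = cm_r[2], cm_z = cm_r[3], cb_y = cb[2], cb_z = cb[3],
      energy = energy
    )
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("stability_curve", class(out))
  attr(out, "mode") <- mode
  attr(out, "rho_water") <- wm$rho
  # characteristic torque: buoyant force times body half-extent, used to
  # recognise curves that are zero up to discretisation noise
  half_extent <- max(purrr::map_dbl(meshes, function(m) {
    max(sqrt(m$vertices[, 2]^2 + m$vertices[, 3]^2))
  })) / 2
  attr(out, "torque_scale") <- wm$rho * wm$g * max(out$v_sub) * half_extent
  out
}

# waterline solve on pre-built meshes (shared with solve_waterline)
solve_waterline_meshes <- function(meshes, mass, wm, tol = 1e-6,
                                   max_iter = 200) {
  zmin <- min(purrr::map_dbl(meshes, ~ min(.x$vertices[, 3])))
  zmax <- max(purrr::map_dbl(meshes, ~ max(.x$vertices[, 3])))
  v_total <- sum(purrr::map_dbl(
    meshes, ~ mesh_volume_centroid(.x$vertices, .x$faces)$volume
  ))
  if (mass > wm$rho * v_total * (1 + tol)) {
    rlang::abort("Body does not float at this orientation.")
  }
  lo <- zmin
  hi <- zmax
  resid <- Inf
  w <- (lo + hi) / 2
  for (i in seq_len(max_iter)) {
    w <- (lo + hi) / 2
    sub <- submerged_properties(meshes, w)
    resid <- wm$rho * sub$volume - mass
    if (abs(resid) <= tol * mass) break
    if (resid > 0) hi <- w else lo <- w
  }
  sub <- submerged_properties(meshes, w)
  new_float_state(
    waterline = w, depth = w - zmin, v_sub = sub$volume,
    cb = sub$centroid, residual = wm$rho * sub$volume - mass,
    converged = abs(resid) <= tol * mass
  )
}

#' Classify the equilibria of a stability curve
#'
#' Locates zero crossings of the sampled torque curve (linear
#' interpolation between samples, periodic in 360 degrees) and classifies
#' each by the local slope: `dtau/dtheta < 0` stable, `> 0` unstable.  A
#' curve that is zero everywhere (relative to its sampling noise floor)
#' is reported as a single neutral equilibrium.
#'
#' @param curve a `stability_curve`.
#' @param tol torques with `|tau|` below `tol * max(|tau|)` are treated
#'   as zero when locating crossings.
#' @param neutral_tol a curve whose largest `|tau|` is below
#'   `neutral_tol` times the characteristic torque (buoyant force times
#'   body half-extent, carried by [righting_moment_curve()]) is zero up
#'   to discretisation noise and reported as neutral everywhere.
#' @return A tibble with `angle` (deg) and `stability`
#'   (`"stable"`/`"unstable"`/`"neutral"`).
#' @export
classify_equilibria <- function(curve, tol = 1e-6, neutral_tol = 1e-4) {
  th <- curve$angle
  ta <- curve$torque
  scale <- max(abs(ta))
  char_scale <- attr(curve, "torque_scale") %||% scale
  if (!is.finite(scale) || scale == 0 || scale <= neutral_tol * char_scale) {
    return(tibble::tibble(angle = NA_real_, stability = "neutral"))
  }
  # close the curve periodically
  th2 <- c(th, th[1] + 360)
  ta2 <- c(ta, ta[1])
  out <- list()
  for (i in seq_len(length(th2) - 1)) {
    t1 <- ta2[i]
    t2 <- ta2[i + 1]
    near0_1 <- abs(t1) <= tol * scale
    if (near0_1) {
      slope <- (t2 - t1) / (th2[i + 1] - th2[i])
      out[[length(out) + 1]] <- tibble::tibble(
        angle = th2[i] %% 360,
        stability = slope_label(slope, tol * scale)
      )
    } else if (sign(t1) != sign(t2) && abs(t2) > tol * scale) {
      root <- th2[i] + (th2[i + 1] - th2[i]) * t1 / (t1 - t2)
      slope <- (t2 - t1) / (th2[i + 1] - th2[i])
      out[[length(out) + 1]] <- tibble::tibble(
        angle = root %% 360,
        stability = slope_label(slope, tol * scale)
      )
    }
  }
  eq <- dplyr::bind_rows(out)
  eq[!duplicated(round(eq$angle, 6)), ]
}

slope_label <- function(slope, tol) {
  if (abs(slope) <= tol) {
    "neutral"
  } else if (slope < 0) {
    "stable"
  } else {
    "unstable"
  }
}
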