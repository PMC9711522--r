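#' Water models
#'
#' Constants for the ambient water: density (freshwater 1000, saltwater
#' 1026 kg/m^3), gravitational acceleration (9.8 m/s^2, matching the
#' study-scale arithmetic rather than 9.80665), and kinematic viscosity
#' (1.0e-6 m^2/s).
#'
#' @param water `"fresh"`, `"salt"`, or a numeric density in kg/m^3.
#' @param g gravitational acceleration (m/s^2).
#' @param nu kinematic viscosity (m^2/s).
#' @return A list with `rho`, `g`, `nu`.
#' @examples
#' water_model("salt")$rho
#' @export
water_model <- function(water = c("fresh", "salt"), g = 9.8, nu = 1.0e-6) {
  rho <- if (is.numeric(water)) {
    water
  } else {
    switch(match.arg(water), fresh = 1000, salt = 1026)
  }
  if (rho <= 0 || g <= 0 || nu <= 0) {
    rlang::abort("Water density, g and viscosity must be strictly positive.")
  }
  list(rho = rho, g = g, nu = nu)
}

# ---- exact clipped volume/centroid of a closed mesh below z = w ----
#
# The solid is decomposed into signed tetrahedra (origin, face); for any
# halfspace H, vol(S  intersect  H) = sum of sign * vol(tet intersect H), because the
# signed tetra indicators sum to the winding number (1 inside, 0 outside).
# Each tetra-halfspace intersection is convex and handled in closed form,
# vectorised by the number of tetra vertices below the plane.

clipped_volume_centroid <- function(v, f, w) {
  n <- nrow(f)
  o <- matrix(0, n, 3)
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  c_ <- v[f[, 3], , drop = FALSE]
  sv <- tet_signed_volumes(a, b, c_)
  s <- sign(sv)
  vg <- abs(sv)

  d <- cbind(w, w - a[, 3], w - b[, 3], w - c_[, 3]) # signed "depth" of each vertex
  below <- d > 0
  nb <- rowSums(below)

  vol <- numeric(n)
  mom <- matrix(0, n, 3)

  # helper: fetch vertex j (1..4 = O,a,b,c) of tets in `rows`
  gather <- function(rows, j) {
    out <- matrix(0, length(rows), 3)
    pick <- function(src, sel) src[rows[sel], , drop = FALSE]
    for (jj in 1:4) {
      sel <- j == jj
      if (any(sel)) {
        out[sel, ] <- switch(jj, o, a, b, c_)[rows[sel], , drop = FALSE]
      }
    }
    out
  }

  idx4 <- nb == 4
  if (any(idx4)) {
    vol[idx4] <- vg[idx4]
    mom[idx4, ] <- vg[idx4] *
      (o[idx4, , drop = FALSE] + a[idx4, , drop = FALSE] +
        b[idx4, , drop = FALSE] + c_[idx4, , drop = FALSE]) / 4
  }

  # lone-vertex tetra: vertex L on one side, M1..M3 on the other
  corner_tet <- function(rows, lone) {
    dl <- d[cbind(rows, lone)]
    others <- matrix(0L, length(rows), 3)
    all4 <- matrix(rep(1:4, each = length(rows)), ncol = 4)
    keep <- all4 != lone
    others <- matrix(t(all4)[t(keep)], ncol = 3, byrow = TRUE)
    lv <- gather(rows, lone)
    frac <- 1
    psum <- lv
    for (k in 1:3) {
      mk <- others[, k]
      dm <- d[cbind(rows, mk)]
      t_ <- dl / (dl - dm)
      frac <- frac * t_
      psum <- psum + lv + t_ * (gather(rows, mk) - lv)
    }
    list(vol = vg[rows] * frac, centroid = psum / 4)
  }

  idx1 <- which(nb == 1)
  if (length(idx1)) {
    lone <- max.col(below[idx1, , drop = FALSE], ties.method = "first")
    ct <- corner_tet(idx1, lone)
    vol[idx1] <- ct$vol
    mom[idx1, ] <- ct$vol * ct$centroid
  }

  idx3 <- which(nb == 3)
  if (length(idx3)) {
    lone <- max.col(!below[idx3, , drop = FALSE], ties.method = "first")
    ct <- corner_tet(idx3, lone) # the part ABOVE the plane
    full_centroid <- (o[idx3, , drop = FALSE] + a[idx3, , drop = FALSE] +
      b[idx3, , drop = FALSE] + c_[idx3, , drop = FALSE]) / 4
    vol[idx3] <- vg[idx3] - ct$vol
    mom[idx3, ] <- vg[idx3] * full_centroid - ct$vol * ct$centroid
  }

  idx2 <- which(nb == 2)
  if (length(idx2)) {
    bmat <- below[idx2, , drop = FALSE]
    i_a <- max.col(bmat, ties.method = "first")
    i_b <- max.col(bmat, ties.method = "last")
    i_c <- max.col(!bmat, ties.method = "first")
    i_d <- max.col(!bmat, ties.method = "last")
    pa <- gather(idx2, i_a)
    pb <- gather(idx2, i_b)
    pc <- gather(idx2, i_c)
    pd <- gather(idx2, i_d)
    da <- d[cbind(idx2, i_a)]
    db <- d[cbind(idx2, i_b)]
    dc <- d[cbind(idx2, i_c)]
    dd <- d[cbind(idx2, i_d)]
    p_ac <- pa + (da / (da - dc)) * (pc - pa)
    p_ad <- pa + (da / (da - dd)) * (pd - pa)
    p_bc <- pb + (db / (db - dc)) * (pc - pb)
    p_bd <- pb + (db / (db - dd)) * (pd - pb)
    g6 <- (pa + pb + p_ac + p_ad + p_bc + p_bd) / 6
    # fan the convex wedge from its interior point over a triangulated
    # boundary: two triangles per original side face, two on the cut
    # face, plus the two end triangles
    tris <- list(
      list(pa, pb, p_bc), list(pa, p_bc, p_ac),
      list(pa, pb, p_bd), list(pa, p_bd, p_ad),
      list(p_ac, p_bc, p_bd), list(p_ac, p_bd, p_ad),
      list(pa, p_ac, p_ad), list(pb, p_bc, p_bd)
    )
    vtot <- numeric(length(idx2))
    mtot <- matrix(0, length(idx2), 3)
    for (tr in tris) {
      vt <- abs(tet_signed_volumes(
        tr[[1]] - g6, tr[[2]] - g6, tr[[3]] - g6
      ))
      vtot <- vtot + vt
      mtot <- mtot + vt * (g6 + tr[[1]] + tr[[2]] + tr[[3]]) / 4
    }
    vol[idx2] <- vtot
    mom[idx2, ] <- mtot
  }

  total <- sum(s * vol)
  list(volume = total, moment = colSums(s * mom))
}

# combined submerged volume/centroid of a list of meshes below z = w
submerged_properties <- function(meshes, w) {
  acc_v <- 0
  acc_m <- c(0, 0, 0)
  for (m in meshes) {
    cl <- clipped_volume_centroid(m$vertices, m$faces, w)
    acc_v <- acc_v + cl$volume
    acc_m <- acc_m + cl$moment
  }
  centroid <- if (acc_v > 0) acc_m / acc_v else c(NA_real_, NA_real_, NA_real_)
  list(volume = acc_v, centroid = centroid)
}

# external (displacement) meshes of a model: every non-air segment
displacement_meshes <- function(x, n = 64, subdivisions = 4) {
  if (inherits(x, "segment_geometry")) {
    return(list(as_mesh(x, n = n, subdivisions = subdivisions)))
  }
  if (inherits(x, "flesh_model")) {
    segs <- purrr::keep(x$segments, ~ .x$role != "air")
    return(purrr::map(segs, ~ as_mesh(.x$geometry, n = n, subdivisions = subdivisions)))
  }
  rlang::abort("Expected a `segment_geometry` or `flesh_model`.")
}

#' Centre of buoyancy
#'
#' Centroid of the displaced volume: the whole body when fully submerged,
#' or the part below a horizontal waterline plane `z = waterline`.  The
#' result depends only on external geometry, never on density partitions.
#'
#' @param x a `segment_geometry` or `flesh_model`.
#' @param waterline waterline height (m); `Inf` means fully submerged.
#' @return A tibble with the displaced volume (m^3) and CB coordinates (m).
#' @examples
#' center_of_buoyancy(mesh_box(1, 1, 1), waterline = 0.5)
#' @export
center_of_buoyancy <- function(x, waterline = Inf) {
  meshes <- displacement_meshes(x)
  if (is.infinite(waterline)) {
    acc_v <- 0
    acc_m <- c(0, 0, 0)
    for (m in meshes) {
      mc <- mesh_volume_centroid(m$vertices, m$faces)
      acc_v <- acc_v + mc$volume
      acc_m <- acc_m + mc$volume * mc$centroid
    }
    cb <- acc_m / acc_v
    return(tibble::tibble(
      v_sub = acc_v, cb_x = cb[1], cb_y = cb[2], cb_z = cb[3]
    ))
  }
  sub <- submerged_properties(meshes, waterline)
  if (!is.finite(sub$volume) || sub$volume <= 0) {
    rlang::abort("Waterline lies below the body: displaced volume is empty.")
  }
  tibble::tibble(
    v_sub = sub$volume,
    cb_x = sub$centroid[1], cb_y = sub$centroid[2], cb_z = sub$centroid[3]
  )
}

#' Displaced volume of a floating body (Archimedes)
#'
#' A floating body displaces water whose weight equals its own:
#' `V_sub = V * rho_body / rho_water`.
#'
#' @param volume whole-body volume (m^3).
#' @param rho_body mean body density (kg/m^3).
#' @param rho_water water density (kg/m^3).
#' @return Displaced volume in m^3.
#' @examples
#' displaced_volume_floating(8.94, 833, 1026)
#' @export
displaced_volume_floating <- function(volume, rho_body, rho_water) {
  if (rho_body <= 0 || rho_water <= 0 || volume <= 0) {
    rlang::abort("Volume and densities must be strictly positive.")
  }
  if (rho_body > rho_water) {
    rlang::abort("Body is denser than water: it sinks; no floating equilibrium.")
  }
  volume * rho_body / rho_water
}

#' Solve the floating waterline
#'
#' Bisection on the waterline height until the displaced mass matches the
#' body mass to a relative tolerance of 1e-6 (at most 200 iterations).
#' The orientation of the body is taken as given; rotate the geometry
#' first to pose it.
#'
#' @param x a `segment_geometry` or `flesh_model`.
#' @param mass body mass (kg); defaults to the model's own mass, and is
#'   required for a bare geometry.
#' @param water a [water_model()] or density in kg/m^3.
#' @param tol relative tolerance on displaced mass.
#' @param max_iter maximum bisection iterations.
#' @return A `float_state` tibble: waterline height `waterline` (m, model
#'   frame), immersion depth `depth` (m above the body's lowest point),
#'   displaced volume `v_sub`, CB coordinates, and the mass residual.
#' @examples
#' solve_waterline(mesh_box(1, 1, 1), mass = 500, water = 1000)
#' @export
solve_waterline <- function(x, mass = NULL, water = "salt",
                            tol = 1e-6, max_iter = 200) {
  wm <- if (is.list(water)) water else water_model(water)
  if (is.null(mass)) {
    if (!inherits(x, "flesh_model")) {
      rlang::abort("`mass` is required when solving for a bare geometry.")
    }
    mass <- mass_properties(x)$mass
  }
  meshes <- displacement_meshes(x)
  zr <- range(purrr::map_dbl(meshes, ~ min(.x$vertices[, 3])),
    purrr::map_dbl(meshes, ~ max(.x$vertices[, 3]))
  )
  v_total <- sum(purrr::map_dbl(
    meshes, ~ mesh_volume_centroid(.x$vertices, .x$faces)$volume
  ))
  m_max <- wm$rho * v_total
  if (mass > m_max * (1 + tol)) {
    rlang::abort("Body does not float: mass exceeds the mass of water it can displace.")
  }
  if (mass >= m_max * (1 - tol)) {
    # neutrally buoyant boundary: fully submerged
    cb <- center_of_buoyancy(x)
    return(new_float_state(
      waterline = zr[2], depth = zr[2] - zr[1], v_sub = v_total,
      cb = c(cb$cb_x, cb$cb_y, cb$cb_z), residual = wm$rho * v_total - mass,
      converged = TRUE
    ))
  }
  lo <- zr[1]
  hi <- zr[2]
  w <- (lo + hi) / 2
  resid <- Inf
  for (i in seq_len(max_iter)) {
    w <- (lo + hi) / 2
    sub <- submerged_properties(meshes, w)
    resid <- wm$rho * sub$volume - mass
    if (abs(resid) <= tol * mass) break
    if (resid > 0) hi <- w else lo <- w
  }
  if (abs(resid) > tol * mass) {
    rlang::abort(sprintf(
      "Waterline solve did not converge in %d iterations (residual %.3g kg).",
      max_iter, resid
    ))
  }
  sub <- submerged_properties(meshes, w)
  new_float_state(
    waterline = w, depth = w - zr[1], v_sub = sub$volume,
    cb = sub$centroid, residual = wm$rho * sub$volume - mass, converged = TRUE
  )
}

new_float_state <- function(waterline, depth, v_sub, cb, residual, converged) {
  out <- tibble::tibble(
    waterline = waterline, depth = depth, v_sub = v_sub,
    cb_x = cb[1], cb_y = cb[2], cb_z = cb[3],
    residual = residual, converged = converged
  )
  class(out) <- c("float_state", class(out))
  out
}

#' Net vertical force on a fully submerged body
#'
#' `F = V * (rho_water - rho_body) * g`: the buoyant excess that must be
#' overcome to hold a positively buoyant body underwater (positive means
#' net lift).
#'
#' @param volume body volume (m^3).
#' @param rho_body mean body density (kg/m^3).
#' @param rho_water water density (kg/m^3).
#' @param g gravitational acceleration (m/s^2).
#' @return Force in newtons.
#' @examples
#' net_vertical_force_submerged(8.94, 833, 1026) # ~16,909 N
#' @export
net_vertical_force_submerged <- function(volume, rho_body, rho_water, g = 9.8) {
  if (any(volume <= 0) || any(rho_body <= 0) || any(rho_water <= 0) ||
    any(g <= 0)) {
    rlang::abort("All inputs must be strictly positive.")
  }
  volume * (rho_water - rho_body) * g
}

#' Dive-force fold ratio
#'
#' How many times the maximum propulsive force the buoyant excess
#' represents: `net_force / max_thrust_force`.
#'
#' @param net_force net buoyant force (N).
#' @param max_thrust_force maximum propulsive force available (N).
#' @return Dimensionless fold ratio.
#' @examples
#' dive_force_ratio(16909, 683) # ~25
#' @export
dive_force_ratio <- function(net_force, max_thrust_force) {
  if (!is.finite(max_thrust_force) || max_thrust_force <= 0) {
    rlang::abort("`max_thrust_force` must be strictly positive.")
  }
  net_force / max_thrust_force
}
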