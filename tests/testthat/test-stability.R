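test_that("a uniform sphere has zero righting torque at every roll angle", {
  sph <- flesh_model(list(body_segment(
    "s", mesh_icosphere(0.5, subdivisions = 3), 800, "axial head-trunk"
  )))
  curve <- righting_moment_curve(sph, angles = seq(0, 330, by = 30))
  scale <- attr(curve, "torque_scale")
  expect_lt(max(abs(curve$torque)) / scale, 1e-4)
  eq <- classify_equilibria(curve)
  expect_identical(eq$stability, "neutral")
})

test_that("a submerged dumbbell follows the F * L * sin(theta) pendulum law", {
  db <- dumbbell_model(offset = 1, r = 0.3)
  props <- mass_properties(db)
  cb <- center_of_buoyancy(db)
  curve <- righting_moment_curve(db,
    angles = seq(0, 350, by = 10),
    mode = "submerged", water = "fresh"
  )
  arm <- cb$cb_z - props$cm_z
  f_b <- 1000 * 9.8 * cb$v_sub
  expected <- f_b * arm * abs(sin(curve$angle * pi / 180))
  expect_lt(max(abs(abs(curve$torque) - expected)), 1e-8 * f_b * arm)
  # CB above CM: upright is the stable hang
  eq <- classify_equilibria(curve)
  expect_identical(eq$stability[eq$angle == 0], "stable")
  expect_identical(eq$stability[eq$angle == 180], "unstable")
})

test_that("bilaterally symmetric floaters have zero torque at 0 and 180 degrees", {
  body <- generate_sailback_body()
  curve <- righting_moment_curve(body, angles = c(0, 180))
  scale <- attr(curve, "torque_scale")
  expect_lt(max(abs(curve$torque)) / scale, 1e-6)
})

test_that("the sail-backed body is unstable upright and stable on its side", {
  body <- generate_sailback_body()
  curve <- righting_moment_curve(body, angles = seq(0, 350, by = 10))
  eq <- classify_equilibria(curve)
  expect_identical(eq$stability[eq$angle == 0], "unstable")
  expect_identical(eq$stability[eq$angle == 180], "unstable")
  side <- eq$angle > 45 & eq$angle < 135
  expect_true(any(side & eq$stability == "stable"))

  # energy-consistency: tau agrees with the downhill direction of the
  # independently tabulated potential energy (finite differences)
  d_energy <- diff(curve$energy) / diff(curve$angle * pi / 180)
  tau_mid <- (curve$torque[-1] + curve$torque[-nrow(curve)]) / 2
  expect_gt(stats::cor(-d_energy, tau_mid), 0.999)
  big <- abs(tau_mid) > 0.2 * max(abs(tau_mid))
  expect_true(all(sign(-d_energy[big]) == sign(tau_mid[big])))
})

test_that("mirrored and reflected geometries mirror the stability curve", {
  up <- generate_sailback_body(n_section = 32)
  dn <- generate_sailback_body(n_section = 32, mirror = TRUE)
  angles <- seq(10, 170, by = 20)
  c_up <- righting_moment_curve(up, angles = angles)
  # bilateral (y) symmetry: tau(-theta) = -tau(theta)
  c_neg <- righting_moment_curve(up, angles = 360 - angles)
  expect_lt(
    max(abs(c_neg$torque + c_up$torque)),
    1e-5 * attr(c_up, "torque_scale")
  )
  # ventrally flipped sail is the same body rolled by 180 degrees
  c_dn <- righting_moment_curve(dn, angles = (angles + 180) %% 360)
  expect_lt(
    max(abs(c_dn$torque - c_up$torque)),
    1e-5 * attr(c_up, "torque_scale")
  )
})

test_that("classification follows the sign of the torque slope at the crossing", {
  mk <- function(tau) {
    th <- seq(0, 350, by = 10)
    structure(
      tibble::tibble(angle = th, torque = tau(th * pi / 180)),
      class = c("stability_curve", "tbl_df", "tbl", "data.frame")
    )
  }
  eq <- classify_equilibria(mk(function(x) -sin(x)))
  expect_identical(eq$stability[eq$angle == 0], "stable")
  expect_identical(eq$stability[eq$angle == 180], "unstable")
  eq <- classify_equilibria(mk(function(x) sin(x)))
  expect_identical(eq$stability[eq$angle == 0], "unstable")
  expect_identical(eq$stability[eq$angle == 180], "stable")
  eq <- classify_equilibria(mk(function(x) 0 * x))
  expect_identical(eq$stability, "neutral")
  # interpolated root location for a crossing between samples
  eq <- classify_equilibria(mk(function(x) cos(x)))
  expect_equal(sort(eq$angle), c(90, 270), tolerance = 0.02)
})
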