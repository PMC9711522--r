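test_that("the thrust-power quadratic evaluates and factors correctly", {
  expect_equal(thrust_power(1.0), -164.93 + 1899.1 - 896.35, tolerance = 1e-12)
  expect_equal(thrust_power(1.0), 837.82, tolerance = 1e-6)
  expect_equal(thrust_power(1.2), 823.246, tolerance = 1e-6)
  roots <- thrust_validity_range()
  expect_equal(roots, c(0.0908, 2.028), tolerance = 1e-3)
  expect_equal(thrust_power(roots[1]), 0, tolerance = 1e-9)
  expect_equal(thrust_power(3, clamp = TRUE), 0)
  expect_equal(thrust_force(1.2), thrust_power(1.2) / 1.2)
  expect_error(thrust_power(-1), "non-negative")
})

test_that("elongated-body thrust matches the period-averaged oracle", {
  kin <- swim_kinematics()
  expect_equal(kin$wave_speed, 0.25 * 0.57 * 13.53, tolerance = 1e-12)

  # independent oracle: time-average of 1/2 m_a [(dh/dt)^2 - U^2 (dh/dx)^2]
  # at the trailing edge over one beat period, by dense quadrature
  oracle <- function(u, kin, rho = 1026) {
    m_a <- pi * rho * kin$span^2 / 4
    t <- seq(0, 1 / kin$frequency, length.out = 40001)[-1]
    dhdt <- -kin$amplitude * kin$omega * cos(kin$omega * t)
    dhdx <- kin$amplitude * kin$k * cos(kin$omega * t)
    mean(0.5 * m_a * (dhdt^2 - u^2 * dhdx^2))
  }
  for (u in c(0, 0.5, 1.0, 1.5, 2.5)) {
    expect_equal(lighthill_thrust(u, kin), oracle(u, kin),
      tolerance = 1e-6
    )
  }
  expect_equal(lighthill_thrust(kin$wave_speed, kin), 0, tolerance = 1e-12)

  u <- seq(0, 3, by = 0.1)
  thr <- lighthill_thrust(u, kin)
  expect_true(all(diff(thr) < 0)) # strictly decreasing in U
  expect_true(all(thr[u < kin$wave_speed] > 0))
  expect_true(all(thr[u > kin$wave_speed] < 0))
})

test_that("drag power is cubic in speed with the undulation multiplier", {
  expect_equal(drag_power(0), 0)
  expect_equal(drag_power(1, drag_model(kappa = 1)), 97.06473, tolerance = 1e-6)
  expect_equal(drag_power(1, drag_model(kappa = 3)), 3 * 97.06473, tolerance = 1e-6)
  u <- c(0.3, 0.7, 1.1)
  expect_equal(drag_power(2 * u), 8 * drag_power(u), tolerance = 1e-12)
  expect_error(drag_model(kappa = 0.5), "at least 1")
})

test_that("maximum speed solves the thrust-drag intersection", {
  # toy closed form: P_t = U, P_d = U^3 meet at exactly 1
  toy_curve <- thrust_curve(0, 1, -1e-9)
  toy_drag <- drag_model(cd = 1, area = 1, rho = 2, kappa = 1) # 1/2*2*1*1 = 1
  expect_equal(max_swim_speed(toy_curve, toy_drag), 1, tolerance = 1e-5)

  u3 <- max_swim_speed(thrust_curve(), drag_model(kappa = 3))
  expect_equal(u3, 1.373, tolerance = 1e-3)
  expect_equal(round(u3, 1), 1.4)

  # grid-scan oracle for kappa = 5: largest sign change of P_t - P_d
  u5 <- max_swim_speed(thrust_curve(), drag_model(kappa = 5))
  grid <- seq(0.05, 2, length.out = 200001)
  gap <- thrust_power(grid) - drag_power(grid, drag_model(kappa = 5))
  crossings <- which(gap[-length(gap)] * gap[-1] <= 0)
  expect_equal(u5, grid[max(crossings)], tolerance = 1e-4)

  kappas <- c(1, 2, 3, 4, 5)
  speeds <- sapply(kappas, function(k) {
    max_swim_speed(thrust_curve(), drag_model(kappa = k))
  })
  expect_true(all(diff(speeds) < 0)) # more drag, slower

  expect_error(
    max_swim_speed(thrust_curve(-1e6, 0, -1), drag_model()),
    "never meets"
  )
})

test_that("Reynolds number is U L / nu", {
  expect_equal(reynolds_number(1, 1, 1), 1)
  expect_equal(reynolds_number(0, 10), 0)
  expect_equal(reynolds_number(2, 3, 1e-6), 6e6)
  expect_error(reynolds_number(1, 1, 0), "positive")
})

test_that("infilling a medullary cavity raises section modulus as q^4/(1-q^4)", {
  expect_equal(bending_strength_gain(0), 0)
  expect_equal(bending_strength_gain(0.5), 100 * 0.0625 / 0.9375, tolerance = 1e-12)
  expect_equal(bending_strength_gain(0.5), 6.67, tolerance = 1e-3)
  # inverse solve for the 35% gain bound, then forward check
  q35 <- (0.35 / 1.35)^0.25
  expect_equal(q35, 0.714, tolerance = 1e-3)
  expect_equal(bending_strength_gain(q35), 35, tolerance = 1e-9)
  q <- seq(0, 0.95, by = 0.05)
  expect_true(all(diff(bending_strength_gain(q)) > 0))
  expect_gt(bending_strength_gain(0.999), 1e4) # diverges toward q = 1
  expect_error(bending_strength_gain(1), "\\[0, 1\\)")
})
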