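test_that("appendage area fractions follow the arithmetic", {
  expect_equal(appendage_area_fraction(numeric(0), 10), 0)
  expect_equal(appendage_area_fraction(c(3.86, 5.29), 54.06),
    (3.86 + 5.29) / 54.06,
    tolerance = 1e-12
  )
  expect_equal(appendage_area_fraction(c(3.86, 5.29), 54.06), 0.1693,
    tolerance = 1e-3
  )
  expect_equal(appendage_area_fraction(10 - 1e-9, 10), 1, tolerance = 1e-9)
  expect_error(appendage_area_fraction(c(6, 6), 10), "exceed")
})

test_that("an exact power law is recovered with a point interval", {
  total <- 10^seq(-1, 2, length.out = 10)
  d <- tibble::tibble(part_area = 2 * total, total_area = total)
  fit <- fit_allometry(d)
  expect_equal(fit$slope, 1, tolerance = 1e-12)
  expect_equal(fit$intercept, log10(2), tolerance = 1e-12)
  expect_lt(diff(fit$ci_slope), 1e-9)
  expect_identical(test_isometry(fit)$verdict, "isometric")

  rma <- fit_allometry(d, method = "rma")
  expect_equal(rma$slope, 1, tolerance = 1e-12)

  td <- tidy(fit)
  expect_identical(td$term, c("intercept", "slope"))
  expect_equal(td$estimate[2], 1, tolerance = 1e-12)
  expect_equal(glance(fit)$nobs, 10L)
  expect_error(fit_allometry(d[1:2, ]), "3")
})

test_that("the fit is scale-invariant in everything but the intercept", {
  d <- generate_allometry_series(n = 25, slope = 0.9, noise_sd = 0.03, seed = 11)
  f1 <- fit_allometry(d)
  d2 <- dplyr::mutate(d,
    part_area = part_area * 1e4, total_area = total_area * 1e4
  )
  f2 <- fit_allometry(d2)
  expect_equal(f2$slope, f1$slope, tolerance = 1e-10)
  expect_equal(f2$se_slope, f1$se_slope, tolerance = 1e-8)
  expect_false(isTRUE(all.equal(f2$intercept, f1$intercept)))
})

test_that("simulated slopes are recovered and shallow slopes detected", {
  # modest replicate count here; the full recovery study runs in the
  # acceptance suite
  slopes <- vapply(1:100, function(s) {
    d <- generate_allometry_series(n = 30, slope = 1, noise_sd = 0.05, seed = s)
    fit_allometry(d)$slope
  }, numeric(1))
  expect_lt(abs(mean(slopes) - 1), 0.01)

  d <- generate_allometry_series(n = 30, slope = 0.67, noise_sd = 0.05, seed = 5)
  iso <- test_isometry(fit_allometry(d))
  expect_identical(iso$verdict, "allometric")
  expect_lt(iso$conf.high, 1)
})

test_that("centrum profiles are classified by their distal ratio trend", {
  const <- tibble::tibble(
    position = 1:10, centrum_length = rep(30, 10), centrum_height = rep(30, 10)
  )
  p <- centrum_profile(const)
  expect_identical(p$classification, "uniform-subquadrate")
  expect_equal(p$distal_slope, 0, tolerance = 1e-12)
  expect_equal(p$profile$ratio, rep(1, 10))

  # ratio rising linearly 1 -> 2 along the tail: slope 1 per unit tail
  rising <- tibble::tibble(
    position = 1:11,
    centrum_height = rep(20, 11),
    centrum_length = 20 * seq(1, 2, length.out = 11)
  )
  p <- centrum_profile(rising)
  expect_identical(p$classification, "distally-elongating")
  expect_equal(p$distal_slope, 1, tolerance = 1e-9)

  falling <- generate_centrum_series("disc", n = 20, seed = 3)
  expect_identical(centrum_profile(falling)$classification, "disc-shortening")

  expect_error(centrum_profile(const[1:4, ]), "5")
  expect_error(
    centrum_profile(dplyr::mutate(const, position = rev(position))),
    "increasing"
  )
})

test_that("centrum classification is invariant to uniform scaling", {
  for (prof in c("uniform", "distally-elongating", "disc")) {
    d <- generate_centrum_series(prof, n = 15, noise_sd = 0.01, seed = 9)
    p1 <- centrum_profile(d)
    d2 <- dplyr::mutate(d,
      centrum_length = centrum_length * 7.3,
      centrum_height = centrum_height * 7.3
    )
    p2 <- centrum_profile(d2)
    expect_identical(p2$classification, p1$classification)
    expect_equal(p2$distal_slope, p1$distal_slope, tolerance = 1e-10)
  }
})
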