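test_that("model assembly conserves mass and mass-weights the CM", {
  asm <- assemble_model(stacked_cubes_model()$segments)
  props <- asm$properties
  whole <- props[props$part == "whole body", ]
  parts <- props[props$part != "whole body", ]
  expect_identical(whole$mass, sum(parts$mass)) # exact, no tolerance
  expect_equal(whole$mass, 1500)
  expect_equal(whole$cm_z, (1000 * 0.5 + 500 * 1.5) / 1500, tolerance = 1e-12)
  expect_equal(whole$cm_z, 0.8333, tolerance = 1e-4)

  single <- flesh_model(list(body_segment(
    "only", frustum_geometry(0.4, 0.2, 1), 900, "axial tail"
  )))
  expect_equal(
    mass_properties(single)[, c("volume", "area", "mass")],
    mass_properties(frustum_geometry(0.4, 0.2, 1), 900)[, c("volume", "area", "mass")]
  )
  expect_error(flesh_model(list()), "at least one")
})

test_that("air segments add volume but never mass", {
  segs <- list(
    body_segment("tissue", box_geometry(1, 1, 1, center = c(0, 0, 0.5)),
      1000, "axial head-trunk"
    ),
    body_segment("lung", box_geometry(0.5, 0.5, 0.5, center = c(0, 0, 0.75)),
      0, "air"
    )
  )
  props <- mass_properties(flesh_model(segs), by_part = TRUE)
  whole <- props[props$part == "whole body", ]
  expect_equal(whole$volume, 1.125)
  expect_equal(whole$mass, 1000)
  expect_equal(whole$cm_z, 0.5) # air is massless, CM stays put
  expect_error(body_segment("bad", box_geometry(1, 1, 1), 500, "air"), "density 0")
  expect_error(
    body_segment("heavy", box_geometry(1, 1, 1), 2500, "axial tail"),
    "2000"
  )
})

test_that("bulk air fraction scales mean density as rho_tissue * (1 - f)", {
  m <- unit_cube_model(density = 952)
  expect_equal(mass_properties(m)$density, 952) # f = 0 leaves it unchanged
  m125 <- apply_air_fraction(m, 0.125)
  expect_equal(mass_properties(m125)$density, 833, tolerance = 1e-12)
  m04 <- apply_air_fraction(m, 0.04)
  expect_equal(mass_properties(m04)$density, 913.92, tolerance = 1e-6)
  # within 1% of the published minimum-air 909
  expect_lt(abs(mass_properties(m04)$density - 909) / 909, 0.01)
  expect_error(apply_air_fraction(m, 1), "\\[0, 1\\)")

  fracs <- seq(0, 0.5, by = 0.1)
  dens <- sapply(fracs, function(f) {
    mass_properties(apply_air_fraction(m, f))$density
  })
  mass <- sapply(fracs, function(f) {
    mass_properties(apply_air_fraction(m, f))$mass
  })
  expect_true(all(diff(dens) < 0))
  expect_true(all(diff(mass) < 0))
})

test_that("the published preset is returned verbatim", {
  p <- spinosaurus_preset()
  expect_equal(p$whole_body$volume, 8.94)
  expect_equal(p$whole_body$area, 54.06)
  expect_equal(p$whole_body$mass, 7390)
  expect_equal(p$whole_body$density, 833)
  expect_equal(p$air_options$fraction, c(0.04, 0.08, 0.125))
  expect_equal(p$air_options$density, c(909, 875, 833))
  expect_equal(p$air_options$mass, c(8013, 7716, 7390))
  expect_equal(p$air_options$cm_x_cm, c(28.5, 23.2, 15.3))
  expect_equal(p$dimensions$metres[p$dimensions$dimension == "total body length"], 13.53)
  expect_equal(p$parts$volume[p$parts$part == "body below waterline (floating)"], 7.27)

  mp <- mass_properties(preset_model("maximum"))
  expect_equal(mp$volume, 8.94)
  expect_equal(mp$area, 54.06)
  expect_equal(mp$mass, 7390)
  expect_equal(mp$density, 833)
  expect_equal(mass_properties(preset_model("minimum"))$mass, 8013)
  by_part <- mass_properties(preset_model(), by_part = TRUE)
  expect_true("trunk sail" %in% by_part$part)
})

test_that("CM reporting is a pure affine re-expression in cm", {
  frame <- reference_frame(acetabulum = c(2.0, 0, 1.2), ground = 0)
  at_origin <- report_cm(c(2.0, 0, 0), frame)
  expect_equal(at_origin$x_cm, 0)
  expect_equal(at_origin$y_cm, 0)
  adult <- report_cm(c(2.153, 0, 2.40), reference_frame(c(2.0, 0, 1.0), 0))
  expect_equal(adult$x_cm, 15.3, tolerance = 1e-9)
  expect_equal(adult$y_cm, 240, tolerance = 1e-9)
  min_air <- report_cm(c(0.285, 0, 2.0), reference_frame(c(0, 0, 2.0), 0))
  expect_equal(min_air$x_cm, 28.5, tolerance = 1e-9)
  expect_error(report_cm(c(0, 0, 0), NULL), "frame")
})

test_that("YAML body configs round-trip through the model builder", {
  cfg <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "posture: bipedal",
    "air: maximum",
    "segments:",
    "  - name: trunk",
    "    kind: ellipsoid",
    "    a: 1.0",
    "    b: 0.5",
    "    c: 0.6",
    "    density: 850",
    "    role: axial head-trunk",
    "  - name: tail",
    "    kind: frustum",
    "    r1: 0.4",
    "    r2: 0.1",
    "    h: 2.0",
    "    density: 1000",
    "    role: axial tail"
  ), cfg)
  model <- read_body_config(cfg)
  expect_s3_class(model, "flesh_model")
  expect_equal(model$air_fraction, 0.125)
  mp <- mass_properties(model, by_part = TRUE)
  expect_equal(nrow(mp), 3)
  v_expected <- 4 / 3 * pi * 0.3 + pi * 2 * (0.16 + 0.04 + 0.01) / 3
  expect_equal(mp$volume[mp$part == "whole body"], v_expected, tolerance = 1e-12)

  out <- withr::local_tempfile(fileext = ".csv")
  write_mass_properties(mp, out)
  back <- utils::read.csv(out)
  expect_equal(back$mass, mp$mass, tolerance = 1e-6)
})
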