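test_that("mass properties of analytic solids match closed forms", {
  cube <- mass_properties(mesh_box(1, 1, 1), density = 1000)
  expect_equal(cube$volume, 1)
  expect_equal(cube$mass, 1000)
  expect_equal(cube$area, 6)
  expect_equal(c(cube$cm_x, cube$cm_y, cube$cm_z), c(0.5, 0.5, 0.5))

  fr <- mass_properties(frustum_geometry(1, 0.5, 2), density = 1000)
  expect_equal(fr$volume, pi * 2 * (1 + 0.5 + 0.25) / 3, tolerance = 1e-12)
  expect_equal(fr$volume, 3.66519, tolerance = 1e-5)
  # cone-limit centroid check via a nearly degenerate top radius
  cone <- mass_properties(frustum_geometry(1, 1e-9, 3), density = 1)
  expect_equal(cone$cm_z, 0.75, tolerance = 1e-6)

  el <- mass_properties(ellipsoid_geometry(1, 1, 1), density = 833)
  expect_equal(el$volume, 4.18879, tolerance = 1e-5)
  expect_equal(el$mass, 3489.3, tolerance = 1e-4)
  expect_equal(el$area, 12.56637, tolerance = 1e-5)
})

test_that("mesh discretisations converge monotonically to the sphere", {
  v_true <- 4 / 3 * pi
  s_true <- 4 * pi
  errs <- sapply(2:5, function(k) {
    mp <- mass_properties(mesh_icosphere(1, subdivisions = k), density = 1)
    c(
      v = abs(mp$volume - v_true) / v_true,
      s = abs(mp$area - s_true) / s_true,
      cm = sqrt(mp$cm_x^2 + mp$cm_y^2 + mp$cm_z^2)
    )
  })
  expect_true(all(diff(errs["v", ]) < 0))
  expect_true(all(diff(errs["s", ]) < 0))
  # level 5 has 20480 faces, past the 10k-face mark
  expect_lt(errs["v", 4], 1e-3)
  expect_lt(errs["s", 4], 1e-3)
  expect_lt(errs["cm", 4], 1e-9)
})

test_that("meshed parametric solids agree with their closed forms", {
  fr <- frustum_geometry(0.8, 0.3, 1.7, base = c(0.2, -0.1, 0.4))
  mp_mesh <- mass_properties(as_mesh(fr, n = 256), density = 1000)
  mp_exact <- mass_properties(fr, density = 1000)
  expect_equal(mp_mesh$volume, mp_exact$volume, tolerance = 1e-3)
  expect_equal(mp_mesh$area, mp_exact$area, tolerance = 1e-3)
  expect_equal(mp_mesh$cm_z, mp_exact$cm_z, tolerance = 1e-3)

  el <- ellipsoid_geometry(1.2, 0.5, 0.8, center = c(1, 2, 3))
  mp_mesh <- mass_properties(as_mesh(el, subdivisions = 5), density = 1000)
  expect_equal(mp_mesh$volume, mass_properties(el, 1)$volume, tolerance = 1e-3)
  expect_equal(mp_mesh$cm_x, 1, tolerance = 1e-9)
})

test_that("rigid transforms preserve volume, area and mass and move the CM covariantly", {
  g <- mesh_frustum(0.6, 0.3, 1.2, n = 48)
  rot <- rotation_z(37) %*% rotation_x(-15)
  tr <- c(0.3, -1.2, 2.0)
  g2 <- transform_geometry(g, rot, tr)
  mp1 <- mass_properties(g, density = 900)
  mp2 <- mass_properties(g2, density = 900)
  expect_equal(mp2$volume, mp1$volume, tolerance = 1e-12)
  expect_equal(mp2$area, mp1$area, tolerance = 1e-12)
  expect_equal(mp2$mass, mp1$mass, tolerance = 1e-12)
  cm_expected <- as.numeric(rot %*% c(mp1$cm_x, mp1$cm_y, mp1$cm_z) + tr)
  expect_equal(c(mp2$cm_x, mp2$cm_y, mp2$cm_z), cm_expected, tolerance = 1e-10)
})

test_that("open or inconsistently oriented meshes are rejected with edge diagnostics", {
  box <- mesh_box(1, 1, 1)
  expect_error(
    mesh_geometry(box$vertices, box$faces[-1, ]),
    "open.*edge", ignore.case = TRUE
  )
  flipped <- box$faces
  flipped[1, ] <- flipped[1, c(1, 3, 2)]
  expect_error(
    mesh_geometry(box$vertices, flipped),
    "edge", ignore.case = TRUE
  )
  expect_error(frustum_geometry(1, -0.5, 2), "positive")
  expect_error(box_geometry(0, 1, 1), "positive")
})

test_that("OBJ and STL round-trips preserve geometry", {
  g <- mesh_frustum(0.5, 0.2, 1, n = 16)
  obj <- withr::local_tempfile(fileext = ".obj")
  write_obj(g, obj)
  g2 <- read_obj(obj)
  expect_equal(
    mass_properties(g2, 1000)$volume,
    mass_properties(g, 1000)$volume,
    tolerance = 1e-6
  )
  stl <- withr::local_tempfile(fileext = ".stl")
  write_stl(g, stl)
  g3 <- read_stl(stl)
  expect_equal(
    mass_properties(g3, 1000)$volume,
    mass_properties(g, 1000)$volume,
    tolerance = 1e-6
  )
  expect_equal(sort(g3$vertices[, 3]), sort(g$vertices[, 3]), tolerance = 1e-6)
})
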