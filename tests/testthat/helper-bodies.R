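# small bodies reused across tests

unit_cube_model <- function(density = 1000) {
  flesh_model(list(body_segment(
    "cube", box_geometry(1, 1, 1, center = c(0.5, 0.5, 0.5)),
    density, "axial head-trunk"
  )))
}

stacked_cubes_model <- function(rho_lower = 1000, rho_upper = 500) {
  flesh_model(list(
    body_segment("lower", box_geometry(1, 1, 1, center = c(0, 0, 0.5)),
      rho_lower, "axial head-trunk"
    ),
    body_segment("upper", box_geometry(1, 1, 1, center = c(0, 0, 1.5)),
      rho_upper, "axial head-trunk"
    )
  ))
}

# two equal spheres on the z axis, one dense and one light: CB at the
# midpoint, CM pulled toward the dense sphere
dumbbell_model <- function(offset = 1, r = 0.3) {
  flesh_model(list(
    body_segment("light", ellipsoid_geometry(r, r, r, center = c(0, 0, offset)),
      200, "axial head-trunk"
    ),
    body_segment("dense", ellipsoid_geometry(r, r, r, center = c(0, 0, -offset)),
      1800, "axial tail"
    )
  ))
}

sphere_cap_volume <- function(d, r = 1) pi * d^2 * (3 * r - d) / 3
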