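Package: paleohydro
Title: Hydrostatics, Hydrodynamics and Comparative Scaling for Digital
    Flesh Models of Extinct Vertebrates
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Build density-partitioned flesh models of extinct vertebrates
    from triangle meshes or parametric segments and compute their mass
    properties (volume, surface area, mass, centre of mass) by exact
    signed-tetrahedron summation.  Solve flotation and buoyancy problems
    (displaced volume, waterline, centre of buoyancy, net diving force,
    roll-stability curves with classified equilibria), estimate undulatory
    swimming performance (elongated-body thrust, drag power with
    undulation multipliers, maximum sustained speed), and run comparative
    scaling analyses (log-log appendage-area allometry with isometry
    tests, caudal centrum proportion profiles).  Includes seeded synthetic
    generators with analytic ground truth for every input, and a preset of
    published summary constants for the adult Spinosaurus aegyptiacus
    flesh model.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
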