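---
title: "Methods: buoyancy, stability and swimming performance of flesh models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: buoyancy, stability and swimming performance of flesh models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paleohydro)
```

This vignette is the package's own account of the science it
implements: the models and their assumptions, the parameters that
matter, what the synthetic generators do and do not emulate, and the
numerical and design choices made where the design was genuinely open.

## The flesh model and its mass properties

A body is represented as an ordered list of segments, each a closed
triangle mesh or a parametric solid (box, conical frustum, ellipsoid)
with a tissue density in (0, 2000] kg/m³ — the plausible span from fat
to compact bone. Air spaces (trachea, lungs, air sacs) are segments of
density zero: they displace water but weigh nothing.

Mesh volume and centre of mass are computed by signed-tetrahedron
(divergence-theorem) summation about the origin, which is exact for
closed, consistently oriented surfaces; validation requires every
directed edge to appear exactly once with its reverse present, and
positive total signed volume. Parametric solids use closed forms. One
deliberate approximation: ellipsoid surface area uses the Thomsen
formula (p = 1.6075, worst error ≈ 1.06%); ellipsoid volume and CM are
exact. Segment overlap is *not* detected — configurations are expected
to tile the body, as density-partitioned flesh models do by
construction.

Aggregate mass is the exact sum of segment masses and the aggregate CM
the mass-weighted mean of segment CMs. A bulk air fraction *f* of
whole-body volume yields mean density ρ̄ = ρ_tissue·(1 − f). The
package also ships a preset of published summary constants for the
adult *Spinosaurus aegyptiacus* model (volume 8.94 m³, area 54.06 m²,
mass 7390 kg, ρ̄ = 833 kg/m³, plus per-part tables and air options).
These are stored verbatim and never recomputed, because the CT-derived
mesh behind them is not an input; the source tables are internally
inexact (part masses sum to 6933 kg, not 7390; 833 × 8.94 = 7447), and
the preset deliberately preserves the printed values without
reconciliation. For the air-fraction arithmetic the airless tissue
density is calibrated from the maximum-air row (833/0.875 = 952 kg/m³);
the minimum- and medium-air rows are then reproduced to within 1%
(913.9 vs 909, 875.8 vs 875), a misfit we accept and assert as a band
rather than hiding.

## Hydrostatics

Floating follows Archimedes: `displaced_volume_floating()` is the
closed form V·ρ_body/ρ_water, and `solve_waterline()` bisects on the
height of a horizontal waterline plane until displaced mass matches
body mass to a relative tolerance of 10⁻⁶ (at most 200 iterations;
bisection rather than Newton because clipped volumes are only piecewise
smooth in the plane height). The submerged volume and its centroid (the
centre of buoyancy) are computed *exactly* for any waterline by
clipping each signed tetrahedron against the halfspace — the
intersection of a tetrahedron with a halfspace is convex and has a
closed-form volume and first moment, so no voxelisation error enters;
the solver's only error is the mass-residual tolerance. Water constants
default to 1000 (fresh) and 1026 kg/m³ (salt) with g = 9.8 m/s²
exactly, matching the arithmetic the headline quantities were printed
with, not 9.80665.

Roll stability rotates the body about its longitudinal (x) axis through
the CM — the standard free-floating formulation; the rotation centre is
otherwise arbitrary and the torque about the CM is what classifies
equilibria. At each angle the waterline is re-solved (a fully submerged
variant is also provided, since a partially emergent sail and a
submerged body are both of interest and the floating/submerged choice
is genuinely open). The reported torque is the component in the +θ
direction, τ = ρ_w·V_sub·g·(y_CB − y_CM), which equals −dE/dθ for the
potential energy E = g·(m·z_CM − ρ_w·V_sub·z_CB); a zero crossing with
dτ/dθ < 0 is stable. We adopted this sign convention (rather than
"positive = restoring") because it is the one under which the
energy-consistency oracle and the slope-based classification agree; the
tests assert the pendulum magnitude |τ| = F_b·L·sin θ on a dumbbell and
the finite-difference energy slope on the sail-backed body.
`classify_equilibria()` interpolates zero crossings linearly between
samples; a curve whose largest |τ| is below 10⁻⁴ of the characteristic
torque (buoyant force × body half-extent) is declared neutral
everywhere, which is how a uniform sphere's discretisation noise is
kept from fabricating equilibria.

## Hydrodynamics

Two thrust modes are deliberately kept apart. The *fitted quadratic*
P_t(U) = −164.93 + 1899.1U − 896.35U² (W; valid where positive, between
U ≈ 0.091 and 2.028 m/s) is canonical for reproducing published
numbers. The *elongated-body* mode computes T̄ = ¼·m_a·A²·(ω² − U²k²)
with trailing-edge virtual mass m_a = πρs²/4 from the kinematic
parameters (defaults: body length 13.53 m, amplitude 0.24 L, wavelength
0.57 L, 0.25 Hz, trailing span 0.87 m — an alligator-compliant tail at
this scale). Direct elongated-body theory with these kinematics does
not reproduce the quadratic, and no fitting procedure for the quadratic
is on record, so conflating them would misattribute provenance; both
are exposed and the discrepancy is documented rather than calibrated
away.

Drag power is κ·½·ρ·S·C_d·U³ with C_d = 0.0035 (turbulent estimate at
Re ≈ 7.5 × 10⁵, a stored constant whose characteristic length is not
derivable from the other defaults) and κ the undulation multiplier.
`max_swim_speed()` sign-scans [0.05, 2] m/s and bisects to 10⁻⁶ m/s,
returning the largest root below the thrust curve's upper zero — the
physically meaningful equilibrium, since the lower crossing is the
unstable low-speed intersection. The submerged solve uses κ = 3, the
low end of the three-to-fivefold range, which is the value consistent
with the reported ≈1.4 m/s; the surface case needs a wave-drag model
that is not specified anywhere we can verify, so surface speed is out
of scope rather than guessed. Thrust force at speed, where needed, is
P_t(U)/U.

## Comparative scaling

Allometry fits regress log₁₀(part area) on log₁₀(total area). OLS is
the default and reduced major axis an option: the line-fitting method
behind the published isometry claim is not stated, so both are offered
and the isometry verdict can be checked for robustness. Isometry for an
area-on-area regression means slope 1 (not 2/3 — both axes are areas).
The verdict is "isometric" iff the expected slope lies in the t-based
95% CI, widened by a float-level epsilon so that exact zero-noise data
(a point CI) contains its own slope.

Centrum profiles use the length:height ratio against normalised tail
position; the trend is the least-squares slope over the distal half,
and the ±0.1 ratio-units-per-tail threshold separating "uniform" from
trending profiles is implementation-chosen — the source material is
qualitative ("subquadrate" vs "spool-shaped") — and is documented as a
tunable argument.

## Synthetic data: what it emulates and what it does not

The generators exist so that every pipeline stage runs against known
truth with no external data. `generate_frustum_body()` produces a
head–neck–trunk–tail chain with exact closed-form volume, mass and CM
computed independently inside the generator; `generate_sailback_body()`
is an elliptical-section hull (default 0.5 m lateral × 0.9 m vertical
semi-axes, 4 m long, 960 kg/m³) with a thin light dorsal sail (1.2 m
tall, 300 kg/m³). Its defaults were chosen once so the floater sits
deep (ρ̄ ≈ 918 kg/m³ in freshwater), leaving a narrow waterplane and a
CM raised toward the CB — the mechanism by which a deep-bodied,
sail-backed floater loses upright stability. Allometry series use
lognormal noise (normal on the log scale, matching the fitting model)
on log-uniform total areas; centrum series implement the three
ratio profiles with distal height taper.

What passing tests on these bodies *show*: the geometric and
hydrostatic machinery is exact to its tolerances, the classifiers
recover generating truth, and the qualitative stability pattern
(upright unstable, side stable) follows from sail-backed geometry. What
they *do not* show: anything about the actual animal's mesh-dependent
numbers — CM position in the reporting frame, the 2.6 m flotation
depth, the ≈5000 N·m righting torque. Those require the original
surface geometry and are echoed only when a user supplies a mesh.

## Problem sizes and determinism

The shipped tests run icospheres up to subdivision 5 (20,480 faces,
where volume and area sit within 10⁻³ of the sphere), stability curves
at 5–30° steps on a ~2300-face hull, and a 1000-replicate slope-recovery
study at n = 30, σ = 0.05 — sizes chosen so the whole suite is a
desk-scale computation. All stochastic generators are seeded through
`withr::with_seed()`, so identical seeds give bit-identical outputs,
and the JSON report writer serialises deterministically.

## Known limitations

- No time-domain rigid-body dynamics: stability is static torque
  curves only.
- No CFD, added-mass simulation of the sail, or wave-resistance model;
  consequently no surface-swimming speed.
- Segment overlap is not subtracted; overlapping displaced volume
  would be double-counted.
- Parametric solids are axis-aligned; posing them rotates a mesh
  discretisation, so posed parametric segments carry mesh-level
  (≤ ~10⁻⁴ relative at the default 256-gon) rather than closed-form
  accuracy.
- The preset reproduces printed constants verbatim, including their
  internal inconsistencies.
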