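#' Tail thrust-power curve
#'
#' `thrust_curve()` holds the quadratic `P_t(U) = c0 + c1 U + c2 U^2`
#' (P in watts, U in m/s).  The default coefficients are the published
#' fit for an adult Spinosaurus aegyptiacus flesh model undulating like
#' an alligator; its physical validity range is the interval between its
#' two positive roots where `P_t > 0`.  `thrust_power()` evaluates the
#' curve; `thrust_force()` is `P_t(U)/U`, the mean thrust force at speed.
#'
#' @param c0,c1,c2 quadratic coefficients.
#' @param u swimming speed (m/s), non-negative; vectorised.
#' @param curve a `thrust_curve`.
#' @param clamp clamp negative power to zero.
#' @return `thrust_power()` returns watts; `thrust_force()` newtons;
#'   `thrust_validity_range()` the two roots of the quadratic (m/s).
#' @examples
#' thrust_power(1.2, thrust_curve()) # ~823 W
#' thrust_validity_range(thrust_curve())
#' @export
thrust_curve <- function(c0 = -164.93, c1 = 1899.1, c2 = -896.35) {
  structure(list(c0 = c0, c1 = c1, c2 = c2), class = "thrust_curve")
}

#' @rdname thrust_curve
#' @export
thrust_power <- function(u, curve = thrust_curve(), clamp = FALSE) {
  if (any(u < 0)) rlang::abort("Speed must be non-negative.")
  p <- curve$c0 + curve$c1 * u + curve$c2 * u^2
  if (clamp) p <- pmax(p, 0)
  p
}

#' @rdname thrust_curve
#' @export
thrust_force <- function(u, curve = thrust_curve()) {
  if (any(u <= 0)) rlang::abort("Speed must be positive for a force at speed.")
  thrust_power(u, curve) / u
}

#' @rdname thrust_curve
#' @export
thrust_validity_range <- function(curve = thrust_curve()) {
  disc <- curve$c1^2 - 4 * curve$c2 * curve$c0
  if (disc < 0 || curve$c2 == 0) {
    rlang::abort("Thrust quadratic has no two real roots.")
  }
  sort(c(
    (-curve$c1 + sqrt(disc)) / (2 * curve$c2),
    (-curve$c1 - sqrt(disc)) / (2 * curve$c2)
  ))
}

#' Undulatory swimming kinematics
#'
#' Parameters of the propulsive body wave, alligator-style defaults at
#' Spinosaurus scale: relative tail-beat amplitude `A/L = 0.24`, relative
#' wavelength `lambda/L = 0.57`, beat frequency 0.25 Hz, and the span of
#' the trailing-edge (distal tail) section, default 0.87 m.  Derived
#' quantities: `A = a L`, `lambda = lambda_rel L`, wavenumber
#' `k = 2 pi / lambda`, angular frequency `omega = 2 pi f`, and the body
#' wave speed `V_wave = omega / k = f * lambda` at which thrust vanishes.
#'
#' @param body_length body length L (m).
#' @param amplitude_rel tail-beat amplitude as a fraction of L.
#' @param wavelength_rel body-wave wavelength as a fraction of L.
#' @param frequency tail-beat frequency (Hz).
#' @param span trailing-edge section span (m).
#' @return A `swim_kinematics` list including the derived quantities.
#' @examples
#' swim_kinematics()$wave_speed # 0.25 * 0.57 * 13.53
#' @export
swim_kinematics <- function(body_length = 13.53, amplitude_rel = 0.24,
                            wavelength_rel = 0.57, frequency = 0.25,
                            span = 0.87) {
  check_positive(c(
    body_length = body_length, amplitude_rel = amplitude_rel,
    wavelength_rel = wavelength_rel, frequency = frequency, span = span
  ))
  amplitude <- amplitude_rel * body_length
  wavelength <- wavelength_rel * body_length
  k <- 2 * pi / wavelength
  omega <- 2 * pi * frequency
  structure(
    list(
      body_length = body_length, amplitude_rel = amplitude_rel,
      wavelength_rel = wavelength_rel, frequency = frequency, span = span,
      amplitude = amplitude, wavelength = wavelength, k = k, omega = omega,
      wave_speed = omega / k
    ),
    class = "swim_kinematics"
  )
}

#' Elongated-body (bulk-momentum) mean thrust
#'
#' Mean thrust of a slender undulating swimmer from the virtual mass and
#' lateral motion of its trailing edge:
#' `T = 1/4 m_a A^2 (omega^2 - U^2 k^2)` with virtual mass per unit
#' length `m_a = pi rho s^2 / 4`.  Thrust is positive below the body
#' wave speed, zero at it, and negative beyond.  `lighthill_power()` is
#' `T * U`.  This is a first-principles mode, deliberately separate from
#' the fitted [thrust_curve()]; with the default kinematics the two do
#' not coincide.
#'
#' @param u swimming speed (m/s); vectorised.
#' @param kinematics a [swim_kinematics()].
#' @param rho water density (kg/m^3).
#' @return Newtons (`lighthill_thrust`) or watts (`lighthill_power`).
#' @examples
#' lighthill_thrust(swim_kinematics()$wave_speed) # 0
#' @export
lighthill_thrust <- function(u, kinematics = swim_kinematics(), rho = 1026) {
  if (any(u < 0)) rlang::abort("Speed must be non-negative.")
  m_a <- pi * rho * kinematics$span^2 / 4
  0.25 * m_a * kinematics$amplitude^2 *
    (kinematics$omega^2 - u^2 * kinematics$k^2)
}

#' @rdname lighthill_thrust
#' @export
lighthill_power <- function(u, kinematics = swim_kinematics(), rho = 1026) {
  lighthill_thrust(u, kinematics, rho) * u
}

#' Drag model and drag power
#'
#' Friction drag on the wetted surface with an undulation multiplier:
#' `P_d = kappa * 1/2 * rho * S * C_d * U^3`.  `kappa` in 3-5 covers the
#' increase of drag over the stationary (rigid, towed) value during tail
#' undulation; `kappa = 1` is the stationary baseline.
#'
#' @param cd drag coefficient (default 0.0035, turbulent estimate).
#' @param area wetted surface area S (m^2, default the adult whole-body
#'   54.06).
#' @param rho water density (kg/m^3).
#' @param kappa undulation multiplier, `>= 1`.
#' @param u swimming speed (m/s); vectorised.
#' @param drag a `drag_model`.
#' @return `drag_power()` returns watts.
#' @examples
#' drag_power(1, drag_model(kappa = 1)) # ~97 W
#' @export
drag_model <- function(cd = 0.0035, area = 54.06, rho = 1026, kappa = 3) {
  check_positive(c(cd = cd, area = area, rho = rho, kappa = kappa))
  if (kappa < 1) rlang::abort("`kappa` must be at least 1.")
  structure(list(cd = cd, area = area, rho = rho, kappa = kappa),
    class = "drag_model"
  )
}

#' @rdname drag_model
#' @export
drag_power <- function(u, drag = drag_model()) {
  if (any(u < 0)) rlang::abort("Speed must be non-negative.")
  drag$kappa * 0.5 * drag$rho * drag$area * drag$cd * u^3
}

#' Maximum sustained swimming speed
#'
#' The speed at which thrust power equals drag power, i.e. constant
#' velocity swimming.  Roots of `P_t(U) - P_d(U)` are bracketed by a
#' sign scan over `[lower, upper]` and refined by bisection to 1e-6 m/s;
#' when several positive roots exist the largest below the thrust
#' curve's upper zero is returned.
#'
#' @param curve a [thrust_curve()].
#' @param drag a [drag_model()].
#' @param lower,upper search bracket (m/s).
#' @param n_scan sign-scan grid size.
#' @param tol bisection tolerance (m/s).
#' @return Speed in m/s.
#' @examples
#' max_swim_speed(thrust_curve(), drag_model(kappa = 3)) # ~1.37
#' @export
max_swim_speed <- function(curve = thrust_curve(), drag = drag_model(),
                           lower = 0.05, upper = 2.0, n_scan = 512,
                           tol = 1e-6) {
  f <- function(u) thrust_power(u, curve) - drag_power(u, drag)
  grid <- seq(lower, upper, length.out = n_scan)
  fv <- f(grid)
  ch <- which(fv[-length(fv)] * fv[-1] <= 0 & is.finite(fv[-1]))
  if (length(ch) == 0) {
    rlang::abort("Thrust never meets drag in the search bracket.")
  }
  upper_zero <- max(thrust_validity_range(curve))
  roots <- vapply(ch, function(i) {
    lo <- grid[i]
    hi <- grid[i + 1]
    flo <- f(lo)
    while (hi - lo > tol) {
      mid <- (lo + hi) / 2
      fm <- f(mid)
      if (sign(fm) == sign(flo) && fm != 0) {
        lo <- mid
        flo <- fm
      } else {
        hi <- mid
      }
    }
    (lo + hi) / 2
  }, numeric(1))
  roots <- roots[roots <= upper_zero + tol]
  if (length(roots) == 0) {
    rlang::abort("No intersection below the thrust curve's upper zero.")
  }
  max(roots)
}

#' Reynolds number
#'
#' `Re = U * L / nu`.
#'
#' @param u speed (m/s).
#' @param length characteristic length (m).
#' @param nu kinematic viscosity (m^2/s).
#' @return Dimensionless Reynolds number.
#' @examples
#' reynolds_number(1, 13.53)
#' @export
reynolds_number <- function(u, length, nu = 1.0e-6) {
  if (nu <= 0) rlang::abort("Viscosity must be strictly positive.")
  u * length / nu
}

#' Bending-strength gain from infilling a medullary cavity
#'
#' Relative gain in the section modulus of a circular beam when its
#' medullary cavity (inner:outer radius ratio `q`) is infilled at equal
#' outer radius: `gain% = 100 q^4 / (1 - q^4)`, from
#' `Z_hollow \eqn{\propto} (r_o^4 - r_i^4)/r_o` versus `Z_solid \eqn{\propto} r_o^4/r_o`.
#'
#' @param q inner:outer radius ratio in `[0, 1)`; vectorised.
#' @return Percent increase of the solid over the hollow section.
#' @examples
#' bending_strength_gain(0.5) # 6.67%
#' @export
bending_strength_gain <- function(q) {
  if (any(!is.finite(q) | q < 0 | q >= 1)) {
    rlang::abort("`q` must lie in [0, 1).")
  }
  100 * q^4 / (1 - q^4)
}

#' Thrust and drag power over a speed grid
#'
#' Convenience tibble for plotting thrust power against stationary,
#' submerged (kappa = 3) and high-undulation (kappa = 5) drag power.
#'
#' @param u speed grid (m/s).
#' @param curve a [thrust_curve()].
#' @param drag a [drag_model()]; its `kappa` is overridden per series.
#' @param kappas undulation multipliers to tabulate.
#' @return A tibble with `u`, `series`, `power`.
#' @export
swim_power_curves <- function(u = seq(0, 2, by = 0.01),
                              curve = thrust_curve(),
                              drag = drag_model(), kappas = c(1, 3, 5)) {
  thrust <- tibble::tibble(
    u = u, series = "thrust", power = thrust_power(u, curve)
  )
  drags <- purrr::map(kappas, function(k) {
    d <- drag
    d$kappa <- k
    tibble::tibble(
      u = u, series = sprintf("drag (kappa = %g)", k),
      power = drag_power(u, d)
    )
  })
  out <- dplyr::bind_rows(thrust, dplyr::bind_rows(drags))
  class(out) <- c("swim_power_curves", class(out))
  out
}
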