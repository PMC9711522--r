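#' Appendage area fraction
#'
#' Fraction of the total body surface area contributed by a set of
#' appendages: `sum(parts) / total`.
#'
#' @param part_areas appendage surface areas (same units as `total`).
#' @param total total body surface area.
#' @return The fraction, in `[0, 1)`.
#' @examples
#' appendage_area_fraction(c(3.86, 5.29), 54.06)
#' @export
appendage_area_fraction <- function(part_areas, total) {
  if (any(part_areas < 0) || total <= 0) {
    rlang::abort("Areas must be positive.")
  }
  s <- sum(part_areas)
  if (s >= total) {
    rlang::abort("Part areas meet or exceed the total body area.")
  }
  s / total
}

#' Log-log area allometry fit
#'
#' Regresses `log10(part area)` on `log10(total area)`.  Ordinary least
#' squares is the default; reduced major axis (RMA, standardised major
#' axis) is available since neither variable is error-free in practice.
#' The slope confidence interval uses the t distribution on `n - 2`
#' degrees of freedom (for RMA the usual large-sample standard error,
#' which equals the OLS slope standard error, is used).
#'
#' @param data a data frame of area pairs.
#' @param part,total columns holding part and total areas (tidy-eval).
#' @param method `"ols"` or `"rma"`.
#' @param conf confidence level for the slope interval.
#' @return An `allometry_fit` with [tidy()]/[glance()] methods.
#' @examples
#' d <- generate_allometry_series(n = 30, slope = 1, seed = 1)
#' fit <- fit_allometry(d, part_area, total_area)
#' tidy(fit)
#' test_isometry(fit)
#' @export
fit_allometry <- function(data, part = "part_area", total = "total_area",
                          method = c("ols", "rma"), conf = 0.95) {
  method <- match.arg(method)
  x <- log10(dplyr::pull(data, {{ total }}))
  y <- log10(dplyr::pull(data, {{ part }}))
  if (anyNA(x) || anyNA(y) || any(!is.finite(x)) || any(!is.finite(y))) {
    rlang::abort("All areas must be positive and finite.")
  }
  n <- length(x)
  if (n < 3) rlang::abort("At least 3 area pairs are required.")
  fit <- stats::lm(y ~ x)
  # zero-noise inputs are legitimate here (exact power laws); muffle
  # only summary.lm's perfect-fit warning
  sm <- withCallingHandlers(
    summary(fit),
    warning = function(w) {
      if (grepl("essentially perfect fit", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    }
  )
  r <- stats::cor(x, y)
  if (method == "ols") {
    slope <- unname(stats::coef(fit)[2])
    intercept <- unname(stats::coef(fit)[1])
    se_slope <- sm$coefficients[2, 2]
    se_intercept <- sm$coefficients[1, 2]
  } else {
    slope <- sign(r) * stats::sd(y) / stats::sd(x)
    if (!is.finite(slope) || slope == 0) {
      rlang::abort("RMA slope is degenerate for these data.")
    }
    intercept <- mean(y) - slope * mean(x)
    # large-sample RMA slope SE coincides with the OLS slope SE
    se_slope <- sm$coefficients[2, 2]
    se_intercept <- sm$coefficients[1, 2]
  }
  tcrit <- stats::qt(1 - (1 - conf) / 2, df = n - 2)
  structure(
    list(
      slope = slope, intercept = intercept,
      se_slope = se_slope, se_intercept = se_intercept,
      conf = conf,
      ci_slope = c(slope - tcrit * se_slope, slope + tcrit * se_slope),
      n = n, method = method, r_squared = sm$r.squared,
      data = tibble::tibble(log_total = x, log_part = y)
    ),
    class = "allometry_fit"
  )
}

#' @export
print.allometry_fit <- function(x, ...) {
  cat(sprintf(
    "Log-log allometry fit (%s, n = %d)\n  slope %.4f [%.4f, %.4f] (%d%% CI), intercept %.4f, R^2 %.4f\n",
    toupper(x$method), x$n, x$slope, x$ci_slope[1], x$ci_slope[2],
    round(x$conf * 100), x$intercept, x$r_squared
  ))
  invisible(x)
}

#' Tidy and glance methods for allometry fits
#'
#' @param x an `allometry_fit`.
#' @param ... unused.
#' @return `tidy()` returns one row per coefficient with standard errors
#'   and the slope confidence interval; `glance()` returns a one-row
#'   model summary.
#' @export
tidy.allometry_fit <- function(x, ...) {
  tibble::tibble(
    term = c("intercept", "slope"),
    estimate = c(x$intercept, x$slope),
    std.error = c(x$se_intercept, x$se_slope),
    conf.low = c(NA_real_, x$ci_slope[1]),
    conf.high = c(NA_real_, x$ci_slope[2])
  )
}

#' @rdname tidy.allometry_fit
#' @export
glance.allometry_fit <- function(x, ...) {
  tibble::tibble(
    r.squared = x$r_squared, slope = x$slope, nobs = x$n,
    method = x$method, conf = x$conf
  )
}

#' Test for isometric area-on-area scaling
#'
#' For an area regressed on an area, geometric similarity predicts a
#' log-log slope of 1; the scaling is called isometric when the expected
#' slope lies inside the fitted slope's confidence interval, allometric
#' otherwise.
#'
#' @param fit an [fit_allometry()] result.
#' @param expected_slope expected slope under isometry (1 for
#'   area-on-area).
#' @return A one-row tibble with the verdict and interval.
#' @export
test_isometry <- function(fit, expected_slope = 1.0) {
  if (!inherits(fit, "allometry_fit")) {
    rlang::abort("`fit` must be an allometry_fit.")
  }
  # widen by a float-level epsilon so an exact zero-noise fit (point CI)
  # still counts its own slope as inside
  eps <- 1e-8 * max(1, abs(fit$slope))
  inside <- expected_slope >= fit$ci_slope[1] - eps &
    expected_slope <= fit$ci_slope[2] + eps
  tibble::tibble(
    verdict = if (inside) "isometric" else "allometric",
    slope = fit$slope,
    conf.low = fit$ci_slope[1],
    conf.high = fit$ci_slope[2],
    expected = expected_slope,
    method = fit$method
  )
}

#' Caudal centrum proportion profile
#'
#' Computes the per-vertebra elongation ratio (centrum length / centrum
#' height) along the tail, the least-squares trend of that ratio against
#' normalised tail position over the distal half, and a qualitative
#' classification: near-zero trend (|slope| <= 0.1 per unit tail length)
#' is `uniform-subquadrate` (the Spinosaurus pattern); a rising trend is
#' `distally-elongating` (the crocodylian/varanid spool trend); a
#' falling trend is `disc-shortening` (the derived piscine pattern of
#' mosasaurs).  The classification is invariant to uniform scaling of
#' all dimensions.
#'
#' @param data a data frame of centrum measurements.
#' @param position,length,height columns with caudal position (strictly
#'   increasing), centrum length and height (tidy-eval; mm or any
#'   consistent unit).
#' @param slope_threshold classification threshold in ratio units per
#'   normalised tail length.
#' @return A `centrum_profile`: list with `profile` (tibble of position,
#'   normalised position, ratio), `distal_slope`, `classification`.
#' @examples
#' d <- generate_centrum_series("uniform", n = 20, seed = 1)
#' centrum_profile(d)$classification
#' @export
centrum_profile <- function(data, position = "position",
                            length = "centrum_length",
                            height = "centrum_height",
                            slope_threshold = 0.1) {
  pos <- dplyr::pull(data, {{ position }})
  len <- dplyr::pull(data, {{ length }})
  hei <- dplyr::pull(data, {{ height }})
  if (NROW(pos) < 5) { # NROW: the `length` formal shadows base::length here
    rlang::abort("At least 5 caudal positions are required.")
  }
  if (any(diff(pos) <= 0)) {
    rlang::abort("Caudal positions must be strictly increasing.")
  }
  if (any(len <= 0) || any(hei <= 0)) {
    rlang::abort("Centrum dimensions must be positive.")
  }
  ratio <- len / hei
  pos_norm <- (pos - min(pos)) / (max(pos) - min(pos))
  distal <- pos_norm >= 0.5
  slope <- unname(stats::coef(
    stats::lm(ratio[distal] ~ pos_norm[distal])
  )[2])
  classification <- if (abs(slope) <= slope_threshold) {
    "uniform-subquadrate"
  } else if (slope > 0) {
    "distally-elongating"
  } else {
    "disc-shortening"
  }
  structure(
    list(
      profile = tibble::tibble(
        position = pos, pos_norm = pos_norm, ratio = ratio
      ),
      distal_slope = slope,
      classification = classification,
      slope_threshold = slope_threshold
    ),
    class = "centrum_profile"
  )
}

#' @export
print.centrum_profile <- function(x, ...) {
  cat(sprintf(
    "Centrum proportion profile: %s (distal trend %.3f per unit tail, threshold %.2f)\n",
    x$classification, x$distal_slope, x$slope_threshold
  ))
  invisible(x)
}
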