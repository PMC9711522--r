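#' Plot methods
#'
#' `autoplot()` methods for the main result types: the roll-stability
#' curve (torque against roll angle with classified equilibria), the
#' thrust/drag power curves over speed, the log-log allometry fit with
#' its regression line, and the centrum proportion profile.
#'
#' @param object a `stability_curve`, `swim_power_curves`,
#'   `allometry_fit` or `centrum_profile`.
#' @param ... unused.
#' @return A ggplot object.
#' @name autoplot-methods
NULL

#' @rdname autoplot-methods
#' @export
autoplot.stability_curve <- function(object, ...) {
  eq <- classify_equilibria(object)
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$angle, y = .data$torque)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = "roll angle (deg)", y = "righting torque (N m)",
      title = "Roll stability curve"
    )
  if (!all(is.na(eq$angle))) {
    eq$torque <- 0
    p <- p + ggplot2::geom_point(
      data = eq,
      ggplot2::aes(x = .data$angle, y = .data$torque, colour = .data$stability),
      size = 3
    )
  }
  p
}

#' @rdname autoplot-methods
#' @export
autoplot.swim_power_curves <- function(object, ...) {
  ggplot2::ggplot(
    object,
    ggplot2::aes(x = .data$u, y = .data$power, colour = .data$series)
  ) +
    ggplot2::geom_line() +
    ggplot2::coord_cartesian(ylim = c(0, NA)) +
    ggplot2::labs(
      x = "swimming speed (m/s)", y = "power (W)",
      title = "Thrust and drag power"
    )
}

#' @rdname autoplot-methods
#' @export
autoplot.allometry_fit <- function(object, ...) {
  ggplot2::ggplot(
    object$data,
    ggplot2::aes(x = .data$log_total, y = .data$log_part)
  ) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(
      intercept = object$intercept, slope = object$slope, colour = "steelblue"
    ) +
    ggplot2::labs(
      x = "log10 total body area", y = "log10 part area",
      title = sprintf(
        "Area allometry (%s slope %.3f)", toupper(object$method), object$slope
      )
    )
}

#' @rdname autoplot-methods
#' @export
autoplot.centrum_profile <- function(object, ...) {
  ggplot2::ggplot(
    object$profile,
    ggplot2::aes(x = .data$pos_norm, y = .data$ratio)
  ) +
    ggplot2::geom_point() +
    ggplot2::geom_line(alpha = 0.4) +
    ggplot2::labs(
      x = "normalised tail position", y = "centrum length : height",
      title = sprintf("Centrum proportions (%s)", object$classification)
    )
}
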