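#' Plot an allometric fit on log10 axes
#'
#' Scatter of the fitted observations with the OLS line and its 95%
#' confidence band, on log10-log10 axes.
#'
#' @param object An `allom_fit` from [fit_power_law()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot allom_fit
#' @export
autoplot.allom_fit <- function(object, ...) {
  df <- object$data
  ggplot2::ggplot(df, ggplot2::aes(x = log10(.data$mass_g),
                                   y = log10(.data$value))) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, linewidth = 0.6,
                         color = "steelblue", fill = "grey80") +
    ggplot2::labs(
      x = expression(log[10] ~ "body mass (g)"),
      y = sprintf("log10 %s", object$trait),
      title = sprintf("%s: b = %.3f [%.3f, %.3f]", object$trait,
                      object$b, object$ci95_b[1L], object$ci95_b[2L]),
      subtitle = if (is.na(object$temperature_c)) NULL else
        sprintf("%g °C, n = %d", object$temperature_c, object$n)
    ) +
    ggplot2::theme_minimal()
}

#' Plot an oxygen trace colored by phase
#'
#' @param trace Trace tibble with `time_s`, `o2_percent_sat` and optionally
#'   `phase`.
#' @return A ggplot object.
#' @export
plot_trace <- function(trace) {
  assert_columns(trace, c("time_s", "o2_percent_sat"), "trace")
  p <- ggplot2::ggplot(trace, ggplot2::aes(x = .data$time_s / 60,
                                           y = .data$o2_percent_sat))
  if ("phase" %in% names(trace)) {
    p <- p + ggplot2::geom_point(ggplot2::aes(color = .data$phase),
                                 size = 0.3)
  } else {
    p <- p + ggplot2::geom_line()
  }
  p +
    ggplot2::labs(x = "time (min)", y = "dissolved O2 (% air saturation)") +
    ggplot2::theme_minimal()
}

#' Slope-and-interval plot for a table of allometric fits
#'
#' Point-range display of allometric slopes with their 95% confidence
#' intervals per trait and temperature, with reference lines at the
#' isometric expectations 0.67 and 1.
#'
#' @param fits Tibble from [fit_allometry()] (columns `trait`,
#'   `temperature_c`, `b`, `ci_low`, `ci_high`).
#' @return A ggplot object.
#' @export
plot_scaling_slopes <- function(fits) {
  assert_columns(fits, c("trait", "temperature_c", "b", "ci_low", "ci_high"),
                 "fits")
  ggplot2::ggplot(fits, ggplot2::aes(x = .data$trait, y = .data$b,
                                     color = factor(.data$temperature_c))) +
    ggplot2::geom_hline(yintercept = c(2 / 3, 1), linetype = "dashed",
                        color = "grey60") +
    ggplot2::geom_pointrange(
      ggplot2::aes(ymin = .data$ci_low, ymax = .data$ci_high),
      position = ggplot2::position_dodge(width = 0.4)
    ) +
    ggplot2::labs(x = NULL, y = "allometric slope b",
                  color = "temperature (°C)") +
    ggplot2::theme_minimal()
}
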