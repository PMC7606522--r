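#' Plot a temperature response curve
#'
#' Effect of a single month at each average temperature, relative to the
#' reference category, with a pointwise 95% delta-method band.
#'
#' @param object A `response_curve`.
#' @param ... Unused.
#' @importFrom ggplot2 autoplot
#' @method autoplot response_curve
#' @export
autoplot.response_curve <- function(object, ...) {
  ref <- attr(object, "reference")
  ggplot2::ggplot(object, ggplot2::aes(x = .data$temp, y = .data$effect)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$effect - 1.96 * .data$se,
                                      ymax = .data$effect + 1.96 * .data$se),
                         alpha = 0.2) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed") +
    ggplot2::geom_vline(xintercept = ref, linetype = "dotted") +
    ggplot2::labs(x = "monthly average temperature (°C)",
                  y = sprintf("effect vs %g °C (σ)", ref),
                  title = sprintf("Temperature response (%s form)",
                                  attr(object, "form")))
}

#' Plot a wasting projection
#'
#' Percent change in wasting prevalence relative to the baseline year per
#' region, with parameter-uncertainty bands when present.
#'
#' @param object A `wasting_projection`.
#' @param ... Unused.
#' @method autoplot wasting_projection
#' @export
autoplot.wasting_projection <- function(object, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$year,
                                            y = .data$pct_change))
  if (all(c("lo", "hi") %in% names(object))) {
    p <- p + ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lo,
                                               ymax = .data$hi),
                                  fill = "steelblue", alpha = 0.25)
  }
  p + ggplot2::geom_line() +
    ggplot2::facet_wrap(~region) +
    ggplot2::labs(x = NULL, y = "change in wasting prevalence (%)",
                  title = "Projected change in wasting vs baseline year")
}

#' Plot the cross-sectional regional fit
#'
#' Regional mean outcome against regional mean temperature, point size
#' proportional to observations, with the weighted quartic fit.
#'
#' @param object A `cross_section_fit`.
#' @param ... Unused.
#' @method autoplot cross_section_fit
#' @export
autoplot.cross_section_fit <- function(object, ...) {
  d <- object$data
  grid <- tibble::tibble(mean_temp = seq(min(d$mean_temp), max(d$mean_temp),
                                         length.out = 200))
  grid$fitted <- stats::predict(object$lm, newdata = grid)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$mean_temp, y = .data$mean_outcome)) +
    ggplot2::geom_point(ggplot2::aes(size = .data$n_obs), alpha = 0.6) +
    ggplot2::geom_line(data = grid, ggplot2::aes(y = .data$fitted),
                       color = "red") +
    ggplot2::labs(x = "regional mean temperature (°C)",
                  y = "regional mean outcome (σ)", size = "children",
                  title = sprintf("Cross-sectional quartic (F = %.1f)",
                                  object$f_statistic))
}
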