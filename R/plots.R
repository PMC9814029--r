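#' Plot a power curve
#'
#' Line plot of predicted power against the swept design dimension, one line
#' per test, with an optional horizontal target-power reference.
#'
#' @param object An [sw_power_curve()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot sw_power_curve
#' @export
autoplot.sw_power_curve <- function(object, ...) {
  over <- attr(object, "over")
  tg <- attr(object, "target")
  long <- tidyr::pivot_longer(as_tibble(object), c("power_z", "power_t"),
                              names_to = "test", values_to = "power",
                              names_prefix = "power_")
  p <- ggplot2::ggplot(long, ggplot2::aes(.data[[over]], .data$power,
                                          colour = .data$test)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(
      x = if (over == "cluster_period_size") "Cluster-period size" else "Clusters",
      y = "Predicted power", colour = "Test"
    ) +
    ggplot2::theme_minimal()
  if (!is.null(tg)) {
    p <- p + ggplot2::geom_hline(yintercept = tg$power, linetype = "dashed")
  }
  p
}

#' Plot empirical minus predicted power for a scenario
#'
#' Dot plot of the simulated-minus-predicted power difference per variance
#' estimator and test, with the Monte Carlo acceptance band shaded.
#'
#' @param object An [run_scenario()] result with `delta != 0`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot sw_scenario_result
#' @export
autoplot.sw_scenario_result <- function(object, ...) {
  cmp <- compare_to_predicted(object)
  ggplot2::ggplot(cmp, ggplot2::aes(.data$variance, .data$difference,
                                    shape = .data$test)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey60") +
    ggplot2::geom_hline(ggplot2::aes(yintercept = .data$margin),
                        linetype = "dashed", colour = "grey40") +
    ggplot2::geom_hline(ggplot2::aes(yintercept = -.data$margin),
                        linetype = "dashed", colour = "grey40") +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "Variance estimator",
                  y = "Empirical - predicted power", shape = "Test") +
    ggplot2::theme_minimal()
}
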