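# ggplot2 visualizations for the main result types.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @exportS3Method
autoplot.gfp_result <- function(object, ...) {
  ggplot2::ggplot(object$gfp,
                  ggplot2::aes(x = .data$time, y = .data$gfp,
                               color = .data$group)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Time (ms)", y = expression(GFP ~ (mu * V)),
                  color = NULL) +
    ggplot2::theme_minimal()
}

#' @exportS3Method
autoplot.free_energy_result <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = interaction(.data$o, .data$mu,
                                                   sep = ","),
                                   y = .data$delta_F,
                                   fill = .data$state)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "(o, mu) state", y = expression(Delta * F ~ (nats)),
                  fill = NULL) +
    ggplot2::theme_minimal()
}

#' Plot the resource/free-energy trade-off curve
#'
#' @param curve Tibble from [boltzmann_curve()].
#' @return A ggplot object.
#' @export
plot_boltzmann_curve <- function(curve) {
  ggplot2::ggplot(curve, ggplot2::aes(x = .data$zeta,
                                      y = .data$neg_delta_F)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = expression(zeta),
                  y = expression(-Delta * F)) +
    ggplot2::theme_minimal()
}

#' Scatter of total free-energy difference against the resource parameter
#'
#' @param report A [run_cohort()] report.
#' @return A ggplot object.
#' @export
plot_cohort_coupling <- function(report) {
  ggplot2::ggplot(report$participants,
                  ggplot2::aes(x = .data$zeta, y = .data$dF_total)) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE) +
    ggplot2::labs(x = expression(zeta),
                  y = expression(Delta * F[Total] ~ (nats))) +
    ggplot2::theme_minimal()
}
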