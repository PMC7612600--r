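#' Plot a power sweep
#'
#' One line per strategy of the rejection rate of the linked hypothesis
#' `H0(1, 1)` against the swept axis (maximum sample size or biomarker-1
#' prevalence), with 95% Monte-Carlo error ribbons.
#'
#' @param object An `umbrella_sweep` tibble from [sweep_power()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.umbrella_sweep <- function(object, ...) {
  xlab <- if (object$axis[1] == "n_max") "Maximum sample size"
          else "Prevalence of biomarker 1"
  ggplot2::ggplot(object, ggplot2::aes(x = .data$value, y = .data$power,
                                       colour = .data$strategy)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = pmax(.data$power - 1.96 * .data$mc_se, 0),
                                      ymax = pmin(.data$power + 1.96 * .data$mc_se, 1),
                                      fill = .data$strategy),
                         alpha = 0.15, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = xlab, y = "Power for H0(1,1)", colour = "Strategy",
                  fill = "Strategy") +
    ggplot2::theme_minimal()
}

#' Plot per-arm allocation of a study
#'
#' Mean accrual per arm across replicates, annotated with the mean response
#' rate.
#'
#' @param object An `umbrella_study`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.umbrella_study <- function(object, ...) {
  ggplot2::ggplot(object$allocation,
                  ggplot2::aes(x = .data$arm, y = .data$mean_n)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(
      label = sprintf("%.0f%% resp", 100 * .data$response_rate)),
      vjust = -0.4, size = 3) +
    ggplot2::labs(x = NULL, y = "Mean patients per arm",
                  title = paste(object$strategy$name, "/",
                                object$scenario$name)) +
    ggplot2::theme_minimal()
}
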