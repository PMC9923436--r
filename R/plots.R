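#' Plot a grouped score distribution
#'
#' Side-by-side bars of difficult and easy counts per score bin.
#'
#' @param object A `score_distribution`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.score_distribution <- function(object, ...) {
  df <- tidyr::pivot_longer(
    as_tibble(object), c("difficult", "easy"),
    names_to = "group", values_to = "n"
  )
  df$bin <- factor(df$bin, levels = object$bin)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$bin, y = .data$n,
                                   fill = .data$group)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "DSP score bin", y = "Procedures", fill = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a diagnostic report
#'
#' Point estimates with confidence intervals for the proportion-scale
#' statistics (sensitivity, specificity, predictive values, accuracy).
#'
#' @param object A `diag_report`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.diag_report <- function(object, ...) {
  df <- dplyr::filter(object$statistics, !.data$statistic %in% c("plr", "nlr"))
  df$statistic <- factor(df$statistic, levels = rev(df$statistic))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$estimate, y = .data$statistic)) +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$lower,
                                          xmax = .data$upper)) +
    ggplot2::scale_x_continuous(labels = function(v) sprintf("%.0f%%", 100 * v),
                                limits = c(0, 1)) +
    ggplot2::labs(x = sprintf("Estimate (%d%% CI)", round(100 * object$level)),
                  y = NULL) +
    ggplot2::theme_minimal()
}
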