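#' End-to-end evaluation of a scored cohort
#'
#' Runs the full performance analysis on a cohort that carries scores and
#' outcome labels: the discrete-score ROC curve with AUC, the Youden-optimal
#' cutoff, the prevalence-weighted efficiency grid, and the diagnostic
#' report at the chosen cutoff (Youden's by default).
#'
#' @param data A cohort with a score column and either a logical `difficult`
#'   column or the outcome columns to derive it from.
#' @param cutoff Cutoff for the 2x2 diagnostic report; `NULL` (default) uses
#'   the Youden-optimal cutoff.
#' @param prevalence Prevalence for the adjusted predictive values and
#'   accuracy; `NULL` uses the cohort's own.
#' @param level Confidence level. Default 0.95.
#' @param score_col Name of the score column. Default `"dsp_score"`.
#' @param efficiency_prevalences Grid of prevalences for
#'   [efficiency_grid()].
#' @return A `dsp_evaluation` list: `roc` (a [roc_curve()]), `youden`
#'   (one-row tibble), `efficiency` (tibble), `report` (a
#'   [diagnostic_report()]), `cutoff`.
#' @examples
#' index_cohort() |> evaluate_scores(prevalence = 0.18)
#' @export
evaluate_scores <- function(data, cutoff = NULL, prevalence = NULL,
                            level = 0.95, score_col = "dsp_score",
                            efficiency_prevalences = c(0.01, 0.05, 0.1, 0.2, 0.3, 0.5)) {
  data <- as_tibble(data)
  if (is.null(data[[score_col]])) {
    abort(paste0("Column '", score_col, "' not found; score the cohort first."))
  }
  if (is.null(data[["difficult"]])) data <- add_difficulty(data)
  scores <- data[[score_col]]
  labels <- data$difficult

  roc <- roc_curve(scores, labels, level = level)
  youden <- youden_cutoff(roc)
  eff <- efficiency_grid(roc, efficiency_prevalences)
  if (is.null(cutoff)) cutoff <- youden$cutoff
  counts <- build_two_by_two(scores, labels, cutoff)
  report <- diagnostic_report(counts, prevalence = prevalence, level = level)

  structure(
    list(roc = roc, youden = youden, efficiency = eff,
         report = report, cutoff = cutoff),
    class = "dsp_evaluation"
  )
}

#' @export
print.dsp_evaluation <- function(x, ...) {
  cat(sprintf("AUC %.3f (%d%% CI %.3f-%.3f)\n", x$roc$auc,
              round(100 * x$roc$level),
              x$roc$auc_ci[["lower"]], x$roc$auc_ci[["upper"]]))
  cat(sprintf("Youden cutoff %d (J = %.3f, sens %.3f, spec %.3f)\n",
              x$youden$cutoff, x$youden$youden_j,
              x$youden$sensitivity, x$youden$specificity))
  cat("Efficiency-optimal cutoffs:\n")
  e <- x$efficiency
  for (i in seq_len(nrow(e))) {
    cat(sprintf("  P = %-4s -> cutoff %d (eff %.3f, sens %.3f, spec %.3f)\n",
                format(e$prevalence[i]), e$cutoff[i], e$efficiency[i],
                e$sensitivity[i], e$specificity[i]))
  }
  cat("\n")
  print(x$report)
  invisible(x)
}

#' @export
glance.dsp_evaluation <- function(x, ...) {
  dplyr::bind_cols(
    glance(x$roc),
    tibble(youden_cutoff = x$youden$cutoff, youden_j = x$youden$youden_j,
           report_cutoff = x$cutoff),
    glance(x$report)
  )
}
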