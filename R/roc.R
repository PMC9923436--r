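#' Discrete-score ROC curve
#'
#' One operating point per candidate cutoff — the distinct observed score
#' values plus one above the maximum (the all-negative point, sensitivity 0 /
#' specificity 1) — under the positivity convention score >= cutoff. The AUC
#' is the trapezoid rule over the ROC vertices `(1 - spec, sens)` with the
#' `(0,0)` and `(1,1)` anchors, which for integer scores equals the
#' Mann-Whitney two-sample rank statistic with half credit for ties. The AUC
#' confidence interval uses the Hanley-McNeil variance formula.
#'
#' @param scores Numeric/integer score vector.
#' @param labels Logical vector, `TRUE` = condition present.
#' @param level Confidence level for the AUC interval. Default 0.95.
#' @return A `roc_curve` object: list with `points` (tibble of `cutoff`,
#'   `sensitivity`, `specificity`, `youden_j`), `auc`, `auc_ci`,
#'   `n_pos`, `n_neg`.
#' @examples
#' roc <- roc_curve(c(0, 1, 2, 3, 4), c(FALSE, FALSE, TRUE, FALSE, TRUE))
#' glance(roc)
#' @export
roc_curve <- function(scores, labels, level = 0.95) {
  stopifnot(length(scores) == length(labels))
  labels <- as.logical(labels)
  if (anyNA(scores) || anyNA(labels)) abort("scores/labels must not be missing.")
  if (all(labels) || !any(labels)) {
    abort("Both outcome classes must be present to build an ROC curve.")
  }
  pos <- scores[labels]
  neg <- scores[!labels]
  cutoffs <- sort(unique(scores))
  cutoffs <- c(cutoffs, max(cutoffs) + 1L)
  points <- tibble(
    cutoff = cutoffs,
    sensitivity = vapply(cutoffs, function(c) mean(pos >= c), numeric(1)),
    specificity = vapply(cutoffs, function(c) mean(neg < c), numeric(1))
  ) |>
    dplyr::mutate(youden_j = .data$sensitivity + .data$specificity - 1)

  # trapezoid over vertices ordered along the curve (cutoff descending)
  fpr <- c(0, rev(1 - points$specificity), 1)
  tpr <- c(0, rev(points$sensitivity), 1)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)

  n1 <- length(pos); n0 <- length(neg)
  q1 <- auc / (2 - auc)
  q2 <- 2 * auc^2 / (1 + auc)
  se <- sqrt((auc * (1 - auc) + (n1 - 1) * (q1 - auc^2) +
                (n0 - 1) * (q2 - auc^2)) / (n1 * n0))
  z <- z_crit(level)
  ci <- c(lower = max(0, auc - z * se), upper = min(1, auc + z * se))

  structure(
    list(points = points, auc = auc, auc_ci = ci, auc_se = se,
         level = level, n_pos = n1, n_neg = n0),
    class = "roc_curve"
  )
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("<roc_curve> %d positives / %d negatives, AUC %.3f (%d%% CI %.3f-%.3f)\n",
              x$n_pos, x$n_neg, x$auc, round(100 * x$level),
              x$auc_ci[["lower"]], x$auc_ci[["upper"]]))
  print(x$points, n = nrow(x$points))
  invisible(x)
}

#' @export
tidy.roc_curve <- function(x, ...) x$points

#' @export
glance.roc_curve <- function(x, ...) {
  tibble(auc = x$auc, auc_lower = x$auc_ci[["lower"]],
         auc_upper = x$auc_ci[["upper"]], auc_se = x$auc_se,
         n_pos = x$n_pos, n_neg = x$n_neg)
}

#' Youden's J optimal cutoff
#'
#' The cutoff maximizing J = sensitivity + specificity - 1; ties are broken
#' toward the smaller cutoff.
#'
#' @param curve A `roc_curve`.
#' @return One-row tibble: `cutoff`, `youden_j`, `sensitivity`, `specificity`.
#' @export
youden_cutoff <- function(curve) {
  stopifnot(inherits(curve, "roc_curve"))
  p <- curve$points
  i <- which.max(p$youden_j)  # which.max takes the first maximum: smaller cutoff
  tibble(cutoff = p$cutoff[i], youden_j = p$youden_j[i],
         sensitivity = p$sensitivity[i], specificity = p$specificity[i])
}

#' Prevalence-weighted efficiency optimal cutoff
#'
#' Efficiency at prevalence P is the expected proportion correctly
#' classified, `eff(c; P) = P * sens(c) + (1 - P) * spec(c)`. The optimal
#' cutoff maximizes it; at P = 0.5 this coincides with Youden's J cutoff
#' (eff = J/2 + 1/2). Ties go to the smaller cutoff.
#'
#' @param curve A `roc_curve`.
#' @param prevalence Condition prevalence P in (0, 1).
#' @return One-row tibble: `prevalence`, `cutoff`, `efficiency`,
#'   `sensitivity`, `specificity`.
#' @export
efficiency_cutoff <- function(curve, prevalence) {
  stopifnot(inherits(curve, "roc_curve"))
  if (prevalence <= 0 || prevalence >= 1) abort("`prevalence` must be in (0, 1).")
  p <- curve$points
  eff <- prevalence * p$sensitivity + (1 - prevalence) * p$specificity
  i <- which.max(eff)
  tibble(prevalence = prevalence, cutoff = p$cutoff[i], efficiency = eff[i],
         sensitivity = p$sensitivity[i], specificity = p$specificity[i])
}

#' @rdname efficiency_cutoff
#' @param prevalences Vector of prevalence values; the default is the
#'   standard reporting grid.
#' @export
efficiency_grid <- function(curve, prevalences = c(0.01, 0.05, 0.1, 0.2, 0.3, 0.5)) {
  purrr::map_dfr(prevalences, ~ efficiency_cutoff(curve, .x))
}

#' Plot an ROC curve
#'
#' Vertices of the discrete-score ROC with the chance diagonal and an AUC
#' annotation.
#'
#' @param object A `roc_curve`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.roc_curve <- function(object, ...) {
  df <- tibble(
    fpr = c(0, rev(1 - object$points$specificity), 1),
    tpr = c(0, rev(object$points$sensitivity), 1)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step(direction = "vh") +
    ggplot2::geom_point() +
    ggplot2::annotate(
      "text", x = 0.7, y = 0.15,
      label = sprintf("AUC = %.3f (%d%% CI %.3f-%.3f)", object$auc,
                      round(100 * object$level),
                      object$auc_ci[["lower"]], object$auc_ci[["upper"]])
    ) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "1 - specificity", y = "Sensitivity") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.roc_curve
#' @param curve A `roc_curve`.
#' @export
plot_roc <- function(curve, ...) autoplot.roc_curve(curve, ...)
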