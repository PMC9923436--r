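#' Build a 2x2 confusion table from scores and outcome labels
#'
#' Positivity convention: a score **at or above** the cutoff is test-positive.
#' (The published Table for the DSP Score labels its rows ">2"/"<2", but the
#' printed counts 53/107/1/139 partition all 300 records and give sensitivity
#' 53/54 at the Youden cutoff of 2, which is only consistent with a >=2 vs <2
#' split; the labels are typographical shorthand.)
#'
#' @param scores Integer score vector.
#' @param labels Logical vector, `TRUE` = condition present (difficult).
#' @param cutoff Positivity cutoff; positive means `score >= cutoff`.
#' @return A `confusion_counts` object: list with `tp`, `fp`, `fn`, `tn`,
#'   `cutoff`.
#' @examples
#' build_two_by_two(c(0, 7), c(FALSE, TRUE), cutoff = 4)
#' @export
build_two_by_two <- function(scores, labels, cutoff) {
  stopifnot(length(scores) == length(labels))
  labels <- as.logical(labels)
  if (anyNA(scores) || anyNA(labels)) abort("scores/labels must not be missing.")
  if (all(labels) || !any(labels)) {
    abort("Both outcome classes must be present; statistics are undefined otherwise.")
  }
  pos <- scores >= cutoff
  confusion_counts(
    tp = sum(pos & labels), fp = sum(pos & !labels),
    fn = sum(!pos & labels), tn = sum(!pos & !labels),
    cutoff = cutoff
  )
}

#' @rdname build_two_by_two
#' @param tp,fp,fn,tn Non-negative cell counts (tp = condition present and
#'   test positive, etc.).
#' @export
confusion_counts <- function(tp, fp, fn, tn, cutoff = NA_integer_) {
  cells <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(cells < 0) || any(cells != round(cells))) {
    abort("Counts must be non-negative integers.")
  }
  if (sum(cells) == 0) abort("Counts must not all be zero.")
  structure(list(tp = as.integer(tp), fp = as.integer(fp),
                 fn = as.integer(fn), tn = as.integer(tn),
                 cutoff = cutoff),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), 2, 2,
              dimnames = list(c("test +", "test -"),
                              c("condition +", "condition -")))
  if (!is.na(x$cutoff)) cat("cutoff: score >=", x$cutoff, "\n")
  print(m)
  invisible(x)
}

#' @export
tidy.confusion_counts <- function(x, ...) {
  tibble(cell = c("tp", "fp", "fn", "tn"),
         n = c(x$tp, x$fp, x$fn, x$tn),
         pct = round(100 * c(x$tp, x$fp, x$fn, x$tn) /
                       (x$tp + x$fp + x$fn + x$tn), 2))
}

# Clopper-Pearson exact binomial interval
clopper_pearson <- function(x, n, level = 0.95) {
  a <- 1 - level
  c(lower = if (x == 0) 0 else qbeta(a / 2, x, n - x + 1),
    upper = if (x == n) 1 else qbeta(1 - a / 2, x + 1, n - x))
}

#' Diagnostic-test statistics with confidence intervals
#'
#' The full 2x2 evaluation: sensitivity and specificity with Clopper-Pearson
#' exact intervals; positive and negative likelihood ratios with Simel
#' log-method intervals; prevalence-adjusted predictive values (Bayes'
#' theorem at the stated prevalence) with Mercaldo logit intervals; and
#' prevalence-weighted accuracy `p*sens + (1-p)*spec` with a Clopper-Pearson
#' interval on the implied number of correct calls at the cohort size. When
#' `prevalence` is the cohort's own `(tp+fn)/total`, the adjusted PPV/NPV and
#' accuracy reduce exactly to `tp/(tp+fp)`, `tn/(tn+fn)` and
#' `(tp+tn)/total`.
#'
#' Zero cells are not continuity-corrected: a specificity of 1 makes the PLR
#' unbounded and a sensitivity of 1 makes the NLR 0, and the affected
#' interval endpoints are reported as 0/`Inf` with a note rather than
#' substituted.
#'
#' @param counts A `confusion_counts` object (or use `tp`/`fp`/`fn`/`tn` via
#'   [confusion_counts()]).
#' @param prevalence Condition prevalence in (0,1) used for PPV/NPV/accuracy;
#'   defaults to the cohort's own `(tp+fn)/total`.
#' @param level Confidence level, default 0.95.
#' @return A `diag_report` object; `tidy()` gives one row per statistic with
#'   `estimate`, `lower`, `upper`, `method`, `note`.
#' @examples
#' rep <- diagnostic_report(confusion_counts(53, 107, 1, 139), prevalence = 0.18)
#' tidy(rep)
#' @export
diagnostic_report <- function(counts, prevalence = NULL, level = 0.95) {
  stopifnot(inherits(counts, "confusion_counts"))
  if (!is.numeric(level) || level <= 0 || level >= 1) {
    abort("`level` must be in (0, 1).")
  }
  tp <- counts$tp; fp <- counts$fp; fn <- counts$fn; tn <- counts$tn
  n1 <- tp + fn; n0 <- fp + tn; total <- n1 + n0
  if (n1 == 0 || n0 == 0) {
    abort("Both condition classes must have at least one record.")
  }
  if (is.null(prevalence)) prevalence <- n1 / total
  if (prevalence <= 0 || prevalence >= 1) {
    abort("`prevalence` must be in (0, 1).")
  }
  z <- z_crit(level)
  p <- prevalence

  sens <- tp / n1
  spec <- tn / n0
  sens_ci <- clopper_pearson(tp, n1, level)
  spec_ci <- clopper_pearson(tn, n0, level)

  # Simel log-method for likelihood ratios
  plr <- if (spec < 1) sens / (1 - spec) else Inf
  plr_note <- NA_character_
  if (!is.finite(plr)) {
    plr_ci <- c(lower = NA_real_, upper = Inf)
    plr_note <- "unbounded: specificity = 1 (fp = 0)"
  } else if (tp == 0) {
    plr_ci <- c(lower = 0, upper = NA_real_)
    plr_note <- "zero cell: tp = 0"
  } else {
    se <- sqrt(1 / tp - 1 / n1 + 1 / fp - 1 / n0)
    plr_ci <- exp(log(plr) + c(lower = -1, upper = 1) * z * se)
  }

  nlr <- if (spec > 0) (1 - sens) / spec else Inf
  nlr_note <- NA_character_
  if (!is.finite(nlr)) {
    nlr_ci <- c(lower = NA_real_, upper = Inf)
    nlr_note <- "undefined: specificity = 0 (tn = 0)"
  } else if (fn == 0) {
    nlr_ci <- c(lower = 0, upper = NA_real_)
    nlr_note <- "zero cell: fn = 0 (NLR = 0)"
  } else {
    se <- sqrt(1 / fn - 1 / n1 + 1 / tn - 1 / n0)
    nlr_ci <- exp(log(nlr) + c(lower = -1, upper = 1) * z * se)
  }

  # prevalence-adjusted predictive values, Mercaldo logit intervals
  ppv <- sens * p / (sens * p + (1 - spec) * (1 - p))
  npv <- spec * (1 - p) / (spec * (1 - p) + (1 - sens) * p)
  ppv_note <- npv_note <- NA_character_
  if (tp > 0 && fp > 0 && tn > 0) {
    v <- (1 - sens) / (n1 * sens) + spec / (n0 * (1 - spec))
    lg <- qlogis(ppv) + c(lower = -1, upper = 1) * z * sqrt(v)
    ppv_ci <- plogis(lg)
  } else {
    ppv_ci <- c(lower = NA_real_, upper = NA_real_)
    ppv_note <- "logit interval undefined at a boundary cell"
  }
  if (tn > 0 && fn > 0 && tp > 0) {
    v <- sens / (n1 * (1 - sens)) + (1 - spec) / (n0 * spec)
    lg <- qlogis(npv) + c(lower = -1, upper = 1) * z * sqrt(v)
    npv_ci <- plogis(lg)
  } else {
    npv_ci <- c(lower = NA_real_, upper = NA_real_)
    npv_note <- "logit interval undefined at a boundary cell"
  }

  acc <- p * sens + (1 - p) * spec
  acc_ci <- clopper_pearson(as.integer(round(acc * total)), total, level)

  stats <- tibble(
    statistic = c("sensitivity", "specificity", "plr", "nlr",
                  "ppv", "npv", "accuracy"),
    estimate = c(sens, spec, plr, nlr, ppv, npv, acc),
    lower = unname(c(sens_ci["lower"], spec_ci["lower"], plr_ci["lower"],
                     nlr_ci["lower"], ppv_ci["lower"], npv_ci["lower"],
                     acc_ci["lower"])),
    upper = unname(c(sens_ci["upper"], spec_ci["upper"], plr_ci["upper"],
                     nlr_ci["upper"], ppv_ci["upper"], npv_ci["upper"],
                     acc_ci["upper"])),
    method = c("Clopper-Pearson", "Clopper-Pearson", "Simel log", "Simel log",
               "Mercaldo logit", "Mercaldo logit", "Clopper-Pearson"),
    note = c(NA, NA, plr_note, nlr_note, ppv_note, npv_note, NA)
  )
  structure(
    list(statistics = stats, prevalence = p, level = level, counts = counts),
    class = "diag_report"
  )
}

#' @export
tidy.diag_report <- function(x, ...) x$statistics

#' @export
glance.diag_report <- function(x, ...) {
  est <- setNames(x$statistics$estimate, x$statistics$statistic)
  tibble(prevalence = x$prevalence, level = x$level,
         sensitivity = est[["sensitivity"]], specificity = est[["specificity"]],
         plr = est[["plr"]], nlr = est[["nlr"]],
         ppv = est[["ppv"]], npv = est[["npv"]], accuracy = est[["accuracy"]])
}

#' @export
print.diag_report <- function(x, ...) {
  cts <- x$counts
  total <- cts$tp + cts$fp + cts$fn + cts$tn
  pc <- function(v) sprintf("%.2f%%", 100 * v)
  cut_lab <- if (!is.na(cts$cutoff)) paste0("score >=", cts$cutoff) else "test"
  cat("Diagnostic report (", cut_lab, ", ", total, " records)\n", sep = "")
  cat(sprintf("  %-10s %12s %12s\n", "", "Condition +", "Condition -"))
  cat(sprintf("  %-10s %5d (%s) %5d (%s)\n", "test +",
              cts$tp, pc(cts$tp / total), cts$fp, pc(cts$fp / total)))
  cat(sprintf("  %-10s %5d (%s) %5d (%s)\n", "test -",
              cts$fn, pc(cts$fn / total), cts$tn, pc(cts$tn / total)))
  cat(sprintf("  Prevalence used: %s\n", pc(x$prevalence)))
  s <- x$statistics
  fmt <- function(stat, v) {
    if (stat %in% c("plr", "nlr")) sprintf("%.2f", v) else pc(v)
  }
  for (i in seq_len(nrow(s))) {
    ci <- if (is.na(s$lower[i]) || is.na(s$upper[i])) {
      s$note[i] %||% "CI unavailable"
    } else {
      paste0(fmt(s$statistic[i], s$lower[i]), "-", fmt(s$statistic[i], s$upper[i]))
    }
    cat(sprintf("  %-12s %8s  %s CI %s\n", s$statistic[i],
                fmt(s$statistic[i], s$estimate[i]),
                sprintf("%d%%", round(100 * x$level)), ci))
  }
  invisible(x)
}

#' Write a diagnostic report as JSON
#'
#' Full-precision statistics, interval endpoints, prevalence and counts.
#'
#' @param report A `diag_report`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_diagnostic_report <- function(report, path) {
  stopifnot(inherits(report, "diag_report"))
  cts <- report$counts
  doc <- list(
    prevalence = report$prevalence,
    level = report$level,
    counts = list(tp = cts$tp, fp = cts$fp, fn = cts$fn, tn = cts$tn,
                  cutoff = cts$cutoff),
    statistics = report$statistics
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}
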