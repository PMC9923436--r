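#' Published operating points of the DSP Score on its index cohort
#'
#' The per-cutoff sensitivity/specificity pairs reported for the
#' 300-procedure index cohort (54 difficult, 246 easy): cutoff 2 at
#' 0.981/0.565 (the Youden point), cutoff 3 at 0.481/0.967, cutoff 4 at
#' 0.037/1.
#'
#' @return A tibble with columns `cutoff`, `sensitivity`, `specificity`.
#' @export
index_operating_points <- function() {
  tibble(
    cutoff = c(2L, 3L, 4L),
    sensitivity = c(0.981, 0.481, 0.037),
    specificity = c(0.565, 0.967, 1.000)
  )
}

#' Reconstruct a grouped score distribution from operating points
#'
#' Inverts printed per-cutoff sensitivity/specificity back to per-group
#' counts over score bins. With consecutive integer cutoffs c1..ck the bins
#' are `<c1`, `=c1`, ..., `=c(k-1)`, `>=ck`. The count of difficult records
#' at or above cutoff c is `round(n_difficult * sens(c))` (and easy below c
#' is `round(n_easy * spec(c))`); bin counts are the successive differences.
#' The inversion is checked: recomputing sensitivity and specificity from
#' the bins must reproduce every input value at its printed precision, and
#' implied counts must be non-negative — otherwise the offending cutoff is
#' reported.
#'
#' @param n_difficult,n_easy Group sizes.
#' @param points Data frame with `cutoff` (consecutive integers),
#'   `sensitivity`, `specificity`; defaults to [index_operating_points()].
#' @param digits Printed precision of the input operating points (decimal
#'   places), used by the consistency check. Default 3.
#' @return A `score_distribution`: tibble with columns `bin`, `score` (the
#'   representative score each bin is placed at), `difficult`, `easy`.
#' @examples
#' reconstruct_distribution(54, 246)
#' @export
reconstruct_distribution <- function(n_difficult, n_easy,
                                     points = index_operating_points(),
                                     digits = 3) {
  stopifnot(n_difficult >= 1, n_easy >= 1)
  points <- dplyr::arrange(as_tibble(points), .data$cutoff)
  k <- nrow(points)
  if (k < 1) abort("`points` must contain at least one operating point.")
  if (k > 1 && any(diff(points$cutoff) != 1)) {
    abort("Operating-point cutoffs must be consecutive integers.")
  }
  if (is.unsorted(rev(points$sensitivity)) ||
      is.unsorted(points$specificity)) {
    abort("Sensitivity must be non-increasing and specificity non-decreasing in the cutoff.")
  }

  d_above <- round(n_difficult * points$sensitivity)  # difficult with score >= cutoff
  e_below <- round(n_easy * points$specificity)       # easy with score < cutoff

  # bins low -> high: below c1, between consecutive cutoffs, at/above ck
  difficult <- c(n_difficult - d_above[1], rev(diff(rev(d_above))), d_above[k])
  easy <- c(e_below[1], diff(e_below), n_easy - e_below[k])

  neg <- which(difficult < 0 | easy < 0)
  if (length(neg)) {
    abort(paste0("Operating points are inconsistent: negative implied count ",
                 "around cutoff ", points$cutoff[min(k, neg)], "."))
  }

  c1 <- points$cutoff[1]; ck <- points$cutoff[k]
  mid <- utils::head(points$cutoff, -1)
  dist <- tibble(
    bin = c(paste0("<", c1), paste0("=", mid, recycle0 = TRUE),
            paste0(">=", ck)),
    score = as.integer(c(c1 - 1L, mid, ck)),
    difficult = as.integer(difficult),
    easy = as.integer(easy)
  )

  # round-trip check against the printed precision
  above_d <- rev(cumsum(rev(dist$difficult)))[-1]
  below_e <- cumsum(dist$easy)[-nrow(dist)]
  sens_chk <- round(above_d / n_difficult, digits)
  spec_chk <- round(below_e / n_easy, digits)
  mism <- which(sens_chk != round(points$sensitivity, digits) |
                  spec_chk != round(points$specificity, digits))
  if (length(mism)) {
    abort(paste0("Reconstruction does not reproduce the printed operating ",
                 "point at cutoff ", points$cutoff[mism[1]],
                 "; the inputs are mutually inconsistent."))
  }
  class(dist) <- c("score_distribution", class(dist))
  dist
}

# deterministic predictor combination for each DSP score value; common
# levels preferred (positioning difficulty is rare, junior performers common)
dsp_combo_for_score <- local({
  tab <- tibble::tibble(
    score = 0:7,
    spine_grade = c(1L, 1L, 2L, 3L, 4L, 3L, 3L, 4L),
    experience = c(">12 months", "<=12 months", "<=12 months", "<=12 months",
                   "<=12 months", ">12 months", "<=12 months", "<=12 months"),
    positioning_difficulty = c(FALSE, FALSE, FALSE, FALSE, FALSE, TRUE, TRUE, TRUE)
  )
  function(score) tab[match(score, tab$score), ]
})

#' Expand a grouped score distribution into a record-level cohort
#'
#' Places every record of each bin at one concrete score (by default the
#' bin's representative: the cutoff value for interior bins, one below the
#' lowest cutoff for the bottom bin, the top cutoff for the top bin) and
#' assigns a deterministic predictor combination realizing that score, plus
#' outcome counts consistent with the group label (difficult: 4 punctures;
#' easy: a single puncture). Re-scoring the expanded cohort therefore
#' reproduces the distribution exactly.
#'
#' The bottom bin's internal composition (e.g. score 0 vs score 1 below a
#' cutoff of 2) is not identifiable from grouped operating points; the
#' default places all of it at the highest score in the bin, and
#' `bin_scores` overrides the placement per bin.
#'
#' @param dist A `score_distribution` from [reconstruct_distribution()].
#' @param bin_scores Optional named integer vector (names = bin labels)
#'   overriding each bin's assigned score; a score outside its bin is an
#'   error.
#' @return A cohort tibble with predictor, outcome and `dsp_score` columns.
#' @examples
#' expand_to_cohort(reconstruct_distribution(54, 246)) |> dplyr::count(difficult)
#' @export
expand_to_cohort <- function(dist, bin_scores = NULL) {
  stopifnot(inherits(dist, "score_distribution"))
  scores <- setNames(dist$score, dist$bin)
  if (!is.null(bin_scores)) {
    unknown <- setdiff(names(bin_scores), dist$bin)
    if (length(unknown)) {
      abort(paste0("Unknown bin label(s): ", paste(unknown, collapse = ", "), "."))
    }
    scores[names(bin_scores)] <- as.integer(bin_scores)
    for (b in names(bin_scores)) {
      ok <- bin_contains(b, bin_scores[[b]])
      if (!ok) {
        abort(paste0("Score ", bin_scores[[b]], " lies outside bin '", b, "'."))
      }
    }
  }
  rows <- purrr::pmap(
    list(dist$bin, scores[dist$bin], dist$difficult, dist$easy),
    function(bin, score, n_diff, n_easy) {
      n <- n_diff + n_easy
      if (n == 0) return(NULL)
      combo <- dsp_combo_for_score(score)
      if (is.na(combo$score)) {
        abort(paste0("No predictor combination realizes score ", score, "."))
      }
      tibble(
        spine_grade = rep(combo$spine_grade, n),
        experience = rep(combo$experience, n),
        positioning_difficulty = rep(combo$positioning_difficulty, n),
        difficult = rep(c(TRUE, FALSE), c(n_diff, n_easy)),
        punctures = rep(c(4L, 1L), c(n_diff, n_easy)),
        passes = rep(c(4L, 1L), c(n_diff, n_easy)),
        handover_declared_difficult = FALSE
      )
    }
  )
  cohort <- dplyr::bind_rows(rows)
  if (nrow(cohort) == 0) {
    return(tibble(id = character(), spine_grade = integer(),
                  experience = character(), positioning_difficulty = logical(),
                  difficult = logical(), punctures = integer(),
                  passes = integer(), handover_declared_difficult = logical(),
                  dsp_score = integer()))
  }
  cohort <- score_cohort(cohort)
  cohort$id <- sprintf("rec%03d", seq_len(nrow(cohort)))
  dplyr::relocate(cohort, "id")
}

bin_contains <- function(bin, score) {
  if (startsWith(bin, ">=")) return(score >= as.integer(sub(">=", "", bin)))
  if (startsWith(bin, "<")) return(score < as.integer(sub("<", "", bin)))
  score == as.integer(sub("=", "", bin))
}

#' The reconstructed DSP index cohort
#'
#' Record-level reconstruction of the 300-procedure index cohort from its
#' published grouped operating points: 54 difficult and 246 easy procedures
#' whose scored 2x2 table at cutoff 2 and per-cutoff operating points match
#' the published values.
#'
#' @inheritParams expand_to_cohort
#' @return A 300-row cohort tibble.
#' @export
index_cohort <- function(bin_scores = NULL) {
  expand_to_cohort(reconstruct_distribution(54, 246), bin_scores = bin_scores)
}
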