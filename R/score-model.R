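#' Coefficient table behind the DSP Score
#'
#' The three predictors of difficult spinal-arachnoid puncture that reached
#' Pr(>|z|) < 0.01 in the neural-network analysis of the 300-procedure index
#' cohort, with their coefficient estimates. Feeding this table to
#' [build_score_model()] reproduces the published DSP Score exactly.
#'
#' @return A tibble with one row per candidate predictor: `predictor`,
#'   `estimate`, `p_value`, `kind` (`"ordinal"` or `"binary"`), and a
#'   list-column `levels` giving the ordered level labels.
#' @examples
#' dsp_coefficients()
#' @export
dsp_coefficients <- function() {
  tibble(
    predictor = c("spine_grade", "experience", "positioning_difficulty"),
    estimate  = c(-2.715, 1.045, -2.98),
    p_value   = c(0.009, 0.009, 0.009),
    kind      = c("ordinal", "binary", "binary"),
    levels    = list(
      c("1", "2", "3", "4"),
      c("<=12 months", ">12 months"),
      c("absent", "present")
    )
  )
}

#' Build an additive integer score model from a coefficient table
#'
#' Mechanically converts model coefficient estimates into an additive integer
#' clinical score by the three-step rule: (1) keep only predictors with
#' `p_value < threshold`; (2) take each retained predictor's maximum weight as
#' its absolute coefficient estimate rounded to the nearest integer
#' (half away from zero); (3) orient the weights by the coefficient sign over
#' the supplied level order — a negative estimate means the score rises with
#' the level (weights 0..max ascending), a positive estimate the reverse
#' (max..0). Ordinal predictors get the linear integer ladder 0..max, which is
#' only well defined when max equals the number of levels minus one; any other
#' case is rejected rather than silently interpolated.
#'
#' @param entries A data frame like [dsp_coefficients()]: columns `predictor`,
#'   `estimate`, `p_value`, `kind` and list-column `levels` (ordered labels).
#' @param threshold Significance threshold on `p_value`; predictors at or
#'   above it are dropped. Default 0.01.
#' @return An object of class `score_model`: a list with a `predictors`
#'   tibble (one row per predictor-level, columns `predictor`, `level`,
#'   `weight`, `estimate`), `min_score`, `max_score` and `threshold`.
#' @examples
#' build_score_model(dsp_coefficients())
#' @seealso [dsp_model()] for the prebuilt DSP Score, [score_cohort()] to
#'   apply a model to records.
#' @export
build_score_model <- function(entries, threshold = 0.01) {
  stopifnot(is.data.frame(entries), nrow(entries) >= 1)
  if (!is.numeric(threshold) || length(threshold) != 1 ||
      threshold <= 0 || threshold >= 1) {
    abort("`threshold` must be a single number in (0, 1).")
  }
  req <- c("predictor", "estimate", "p_value", "kind", "levels")
  missing_cols <- setdiff(req, names(entries))
  if (length(missing_cols)) {
    abort(paste0("`entries` is missing column(s): ",
                 paste(missing_cols, collapse = ", "), "."))
  }
  if (any(entries$p_value < 0 | entries$p_value > 1)) {
    abort("`p_value` must lie in [0, 1].")
  }

  kept <- entries[entries$p_value < threshold, , drop = FALSE]
  if (nrow(kept) == 0) {
    abort(paste0("No predictor has p_value below the threshold ", threshold,
                 "; the score would be empty."))
  }

  rows <- purrr::pmap(kept, function(predictor, estimate, p_value, kind, levels) {
    levels <- as.character(levels)
    n_lev <- length(levels)
    if (n_lev < 2) {
      abort(paste0("Predictor '", predictor, "' has fewer than 2 levels."))
    }
    if (anyDuplicated(levels)) {
      abort(paste0("Predictor '", predictor, "' has duplicated level labels."))
    }
    max_w <- as.integer(round_half_away(abs(estimate)))
    if (max_w == 0) {
      abort(paste0(
        "Predictor '", predictor, "' has |estimate| ", abs(estimate),
        " which rounds to a weight of 0; a retained predictor must carry ",
        "at least one point."
      ))
    }
    if (kind == "ordinal" && max_w != n_lev - 1L) {
      abort(paste0(
        "Ordinal predictor '", predictor, "': rounded |estimate| (", max_w,
        ") does not equal the number of levels minus one (", n_lev - 1L,
        "), so the linear 0..max weight ladder is undefined. Recode the ",
        "levels or supply explicit weights."
      ))
    }
    weights <- if (kind == "ordinal") {
      seq(0L, max_w)
    } else {
      c(0L, max_w)
    }
    # sign rule: negative estimate -> score increases along the level order
    if (estimate > 0) weights <- rev(weights)
    tibble(predictor = predictor, level = levels,
           weight = as.integer(weights), estimate = estimate)
  })

  predictors <- dplyr::bind_rows(rows)
  per_pred <- predictors |>
    dplyr::group_by(.data$predictor) |>
    dplyr::summarise(lo = min(.data$weight), hi = max(.data$weight))

  structure(
    list(
      predictors = predictors,
      min_score  = as.integer(sum(per_pred$lo)),
      max_score  = as.integer(sum(per_pred$hi)),
      threshold  = threshold
    ),
    class = "score_model"
  )
}

#' The built-in DSP Score model
#'
#' The Difficult Spinal-Arachnoid Puncture Score: spine grade 1-4 scored
#' 0/1/2/3, performer experience of at most one year scored 1, positioning
#' difficulty present scored 3; aggregate range 0-7. Built on the fly from
#' [dsp_coefficients()] by [build_score_model()], so the published weight
#' table and the mechanical construction rule cannot drift apart.
#'
#' @return A `score_model` object.
#' @examples
#' dsp_model()
#' @export
dsp_model <- function() {
  build_score_model(dsp_coefficients(), threshold = 0.01)
}

#' @export
print.score_model <- function(x, ...) {
  cat("<score_model> ", dplyr::n_distinct(x$predictors$predictor),
      " predictors, score range ", x$min_score, "-", x$max_score,
      " (p < ", format(x$threshold), ")\n", sep = "")
  print(x$predictors, n = nrow(x$predictors))
  invisible(x)
}

#' @describeIn build_score_model `tidy()` returns the per-level weight table.
#' @param x A `score_model`.
#' @param ... Unused.
#' @export
tidy.score_model <- function(x, ...) x$predictors

#' @describeIn build_score_model `glance()` returns a one-row model summary.
#' @export
glance.score_model <- function(x, ...) {
  tibble(
    n_predictors = dplyr::n_distinct(x$predictors$predictor),
    min_score = x$min_score,
    max_score = x$max_score,
    threshold = x$threshold
  )
}

#' Serialize a score model to JSON / read it back
#'
#' The JSON document carries predictor names, ordered levels, integer weights
#' and the provenance coefficient estimates, so non-DSP scores can be defined
#' externally and loaded.
#'
#' @param model A `score_model`.
#' @param path File path.
#' @return `read_score_model()` returns a `score_model`;
#'   `write_score_model()` returns `path` invisibly.
#' @export
write_score_model <- function(model, path) {
  stopifnot(inherits(model, "score_model"))
  preds <- model$predictors |>
    dplyr::group_by(.data$predictor) |>
    dplyr::summarise(
      estimate = .data$estimate[1],
      levels = list(.data$level),
      weights = list(.data$weight)
    )
  doc <- list(
    type = "score_model",
    threshold = model$threshold,
    predictors = purrr::pmap(preds, function(predictor, estimate, levels, weights) {
      list(name = predictor, estimate = estimate,
           levels = levels, weights = weights)
    })
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_score_model
#' @export
read_score_model <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  if (is.null(doc$predictors) || !length(doc$predictors)) {
    abort("Not a score-model JSON document: no predictors found.")
  }
  predictors <- dplyr::bind_rows(purrr::map(doc$predictors, function(p) {
    w <- as.integer(unlist(p$weights))
    if (min(w) != 0L) abort(paste0("Predictor '", p$name,
                                   "': minimum weight must be 0."))
    tibble(predictor = p$name, level = as.character(unlist(p$levels)),
           weight = w, estimate = as.numeric(p$estimate %||% NA_real_))
  }))
  per_pred <- predictors |>
    dplyr::group_by(.data$predictor) |>
    dplyr::summarise(lo = min(.data$weight), hi = max(.data$weight))
  structure(
    list(predictors = predictors,
         min_score = as.integer(sum(per_pred$lo)),
         max_score = as.integer(sum(per_pred$hi)),
         threshold = doc$threshold %||% NA_real_),
    class = "score_model"
  )
}
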