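#' Apply a score model to patient records
#'
#' Adds a `dsp_score` column: the sum over the model's predictors of the
#' weight matched to each record's level. Each model predictor must exist as
#' a column of `data`; values are matched to the model's level labels after a
#' light coercion (logicals become `"absent"`/`"present"`, numbers their
#' decimal string, factors their labels). A missing or unrecognized level is
#' an error naming the offending column and rows — records are never scored
#' on partial information.
#'
#' @param data A data frame of patient records (e.g. from [read_cohort()] or
#'   [simulate_cohort()]).
#' @param model A `score_model`; defaults to the built-in DSP Score.
#' @param col Name of the output column. Default `"dsp_score"`.
#' @return `data` as a tibble with the integer score column appended.
#' @examples
#' tibble::tibble(
#'   spine_grade = c(1, 4, 3),
#'   experience = c(">12 months", "<=12 months", "<=12 months"),
#'   positioning_difficulty = c(FALSE, TRUE, FALSE)
#' ) |> score_cohort()
#' @export
score_cohort <- function(data, model = dsp_model(), col = "dsp_score") {
  stopifnot(is.data.frame(data), inherits(model, "score_model"))
  data <- as_tibble(data)
  pred_names <- unique(model$predictors$predictor)
  missing_cols <- setdiff(pred_names, names(data))
  if (length(missing_cols)) {
    abort(paste0("Records are missing predictor column(s): ",
                 paste(missing_cols, collapse = ", "), "."))
  }
  total <- rep(0L, nrow(data))
  for (p in pred_names) {
    lev_tab <- model$predictors[model$predictors$predictor == p, ]
    vals <- as_level(data[[p]])
    w <- lev_tab$weight[match(vals, lev_tab$level)]
    bad <- which(is.na(w))
    if (length(bad)) {
      abort(paste0(
        "Column '", p, "' has value(s) outside the model's levels {",
        paste(lev_tab$level, collapse = ", "), "} at row(s) ",
        paste(utils::head(bad, 5), collapse = ", "),
        if (length(bad) > 5) paste0(" (and ", length(bad) - 5, " more)"), "."
      ))
    }
    total <- total + w
  }
  data[[col]] <- as.integer(total)
  data
}

# coerce a record column onto the model's character level labels
as_level <- function(x) {
  if (is.logical(x)) return(ifelse(x, "present", "absent"))
  if (is.factor(x)) return(as.character(x))
  if (is.numeric(x)) return(format(x, trim = TRUE, scientific = FALSE))
  as.character(x)
}

#' Score a single predictor combination
#'
#' Convenience wrapper over [score_cohort()] for scalar inputs; vectorized
#' over its arguments.
#'
#' @param spine_grade Spine grade 1-4 (spinous-process palpability grading).
#' @param experience `"<=12 months"` or `">12 months"` of performer
#'   experience (`TRUE` is accepted for `<=12 months`).
#' @param positioning_difficulty Logical: was positioning difficult?
#' @return Integer DSP scores in 0-7.
#' @examples
#' dsp_score(4, "<=12 months", TRUE)   # worst case: 7
#' dsp_score(1, ">12 months", FALSE)   # best case: 0
#' @export
dsp_score <- function(spine_grade, experience, positioning_difficulty) {
  if (is.logical(experience)) {
    experience <- ifelse(experience, "<=12 months", ">12 months")
  }
  df <- tibble(
    spine_grade = spine_grade,
    experience = experience,
    positioning_difficulty = positioning_difficulty
  )
  score_cohort(df)$dsp_score
}
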