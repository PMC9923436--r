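#' Classify a procedure as difficult
#'
#' A spinal-arachnoid puncture is difficult when it needed more than three
#' punctures, exactly three punctures with more than six passes, or when the
#' performer handed the procedure over after the second puncture deeming it
#' difficult. A puncture is a new skin/interspace needle entry; a pass is an
#' advancement or redirection within one puncture, so `passes >= punctures`
#' always — records violating that are rejected as inconsistent.
#'
#' @param punctures Integer vector, number of punctures (>= 1).
#' @param passes Integer vector, number of needle passes (>= punctures).
#' @param handover Logical vector: performer handed over after the second
#'   puncture and declared the procedure difficult. Default `FALSE`.
#' @return Logical vector, `TRUE` for difficult.
#' @examples
#' classify_difficult(4, 4)                 # > 3 punctures
#' classify_difficult(3, 7)                 # 3 punctures, > 6 passes
#' classify_difficult(3, 6)                 # just inside both limits: easy
#' classify_difficult(2, 2, handover = TRUE)
#' @export
classify_difficult <- function(punctures, passes, handover = FALSE) {
  n <- max(length(punctures), length(passes), length(handover))
  punctures <- rep_len(as.integer(punctures), n)
  passes <- rep_len(as.integer(passes), n)
  handover <- rep_len(as.logical(handover), n)
  if (anyNA(punctures) || anyNA(passes) || anyNA(handover)) {
    abort("Outcome fields (punctures, passes, handover) must not be missing.")
  }
  if (any(punctures < 1L)) abort("`punctures` must be >= 1.")
  bad <- which(passes < punctures)
  if (length(bad)) {
    abort(paste0("Inconsistent outcome: passes < punctures at position(s) ",
                 paste(utils::head(bad, 5), collapse = ", "), "."))
  }
  punctures > 3L | (punctures == 3L & passes > 6L) | handover
}

#' Add the difficult-procedure label to a cohort
#'
#' Appends a logical `difficult` column computed by [classify_difficult()]
#' from the `punctures`, `passes` and `handover_declared_difficult` columns.
#'
#' @param data A data frame with outcome columns.
#' @return `data` as a tibble with `difficult` appended.
#' @export
add_difficulty <- function(data) {
  data <- as_tibble(data)
  need <- c("punctures", "passes")
  missing_cols <- setdiff(need, names(data))
  if (length(missing_cols)) {
    abort(paste0("Missing outcome column(s): ",
                 paste(missing_cols, collapse = ", "), "."))
  }
  handover <- data[["handover_declared_difficult"]] %||% FALSE
  data$difficult <- classify_difficult(data$punctures, data$passes, handover)
  data
}

cohort_required_cols <- c("spine_grade", "experience", "positioning_difficulty")

#' Read / write a procedure cohort CSV
#'
#' Cohorts are plain CSV (RFC 4180, UTF-8, header required). The predictor
#' columns `spine_grade` (1-4), `experience` (`"<=12 months"`/`">12 months"`)
#' and `positioning_difficulty` (logical) are mandatory; demographics (`id`,
#' `age`, `sex`, `height`, `weight`, `bmi`, `asa_class`, `urgency`,
#' `tls_contour`, `spine_deformity`, `position`) and outcome columns
#' (`punctures`, `passes`, `handover_declared_difficult`) are optional, and
#' unknown columns are preserved on round-trip. Validation failures are
#' reported with row numbers.
#'
#' @param path CSV file path.
#' @return `read_cohort()` returns a validated tibble; `write_cohort()`
#'   returns `path` invisibly.
#' @export
read_cohort <- function(path) {
  data <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  validate_cohort(data)
}

#' @rdname read_cohort
#' @param data A cohort data frame.
#' @export
write_cohort <- function(data, path) {
  readr::write_csv(as_tibble(data), path, progress = FALSE)
  invisible(path)
}

#' @rdname read_cohort
#' @export
validate_cohort <- function(data) {
  data <- as_tibble(data)
  missing_cols <- setdiff(cohort_required_cols, names(data))
  if (length(missing_cols)) {
    abort(paste0("Cohort is missing mandatory column(s): ",
                 paste(missing_cols, collapse = ", "), "."))
  }
  fail <- function(rows, what) {
    abort(paste0("Invalid cohort: ", what, " at row(s) ",
                 paste(utils::head(rows, 5), collapse = ", "),
                 if (length(rows) > 5) paste0(" (and ", length(rows) - 5, " more)"),
                 "."))
  }
  bad <- which(!(data$spine_grade %in% 1:4))
  if (length(bad)) fail(bad, "spine_grade outside {1,2,3,4}")
  if (anyNA(data$experience) || anyNA(data$positioning_difficulty)) {
    bad <- which(is.na(data$experience) | is.na(data$positioning_difficulty))
    fail(bad, "missing predictor value")
  }
  if (!is.null(data[["id"]]) && anyDuplicated(data$id)) {
    fail(which(duplicated(data$id)), "duplicated id")
  }
  if (all(c("punctures", "passes") %in% names(data))) {
    bad <- which(data$passes < data$punctures)
    if (length(bad)) fail(bad, "passes < punctures")
  }
  if (all(c("bmi", "height", "weight") %in% names(data))) {
    implied <- data$weight / (data$height / 100)^2
    bad <- which(!is.na(data$bmi) & abs(data$bmi - implied) > 0.5)
    if (length(bad)) fail(bad, "bmi inconsistent with height/weight (> 0.5 off)")
  }
  data
}

#' Per-group marginal summaries of a cohort
#'
#' Counts and percentages per level of each categorical variable, and mean
#' and SD of each continuous variable, split by the difficult/easy outcome —
#' the standard cohort-characteristics table (percentages to 2 decimals).
#' Hypothesis tests are deliberately not computed.
#'
#' @param data A cohort with outcome columns (or an existing `difficult`
#'   column).
#' @return A tibble with columns `variable`, `level`, `group`, `n`, `pct`,
#'   `mean`, `sd`; `level`/`pct` are `NA` for continuous variables, `mean`/`sd`
#'   for categorical ones.
#' @export
cohort_marginals <- function(data) {
  data <- as_tibble(data)
  if (is.null(data[["difficult"]])) data <- add_difficulty(data)
  grp <- ifelse(data$difficult, "difficult", "easy")
  group_n <- c(difficult = sum(grp == "difficult"), easy = sum(grp == "easy"))
  vars <- setdiff(names(data),
                  c("id", "difficult", "punctures", "passes",
                    "handover_declared_difficult"))
  out <- purrr::map(vars, function(v) {
    x <- data[[v]]
    if (is.numeric(x) && dplyr::n_distinct(x) > 8) {
      tibble(
        variable = v, level = NA_character_,
        group = c("difficult", "easy"),
        n = unname(group_n), pct = NA_real_,
        mean = c(mean(x[grp == "difficult"]), mean(x[grp == "easy"])),
        sd = c(stats::sd(x[grp == "difficult"]), stats::sd(x[grp == "easy"]))
      )
    } else {
      lv <- as_level(x)
      tidyr::expand_grid(level = sort(unique(lv)),
                         group = c("difficult", "easy")) |>
        dplyr::mutate(
          variable = v,
          n = purrr::map2_int(.data$level, .data$group,
                              function(l, g) sum(lv == l & grp == g)),
          pct = round(100 * .data$n / pmax(1L, group_n[.data$group]), 2),
          mean = NA_real_, sd = NA_real_
        ) |>
        dplyr::select("variable", "level", "group", "n", "pct", "mean", "sd")
    }
  })
  dplyr::bind_rows(out)
}
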