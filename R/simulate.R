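#' Configuration for the synthetic-cohort generator
#'
#' Defaults emulate the 300-procedure index cohort: predictor marginals from
#' its pooled counts (spine grades 95/148/52/5 of 300, performer experience
#' <=12 months 196/300, positioning difficulty 12/300), a latent logistic
#' difficulty model on the three score predictors with coefficient signs
#' matching the reported estimates (higher spine grade, junior performer and
#' positioning difficulty all raise the difficulty odds), and an intercept
#' calibrated so the expected difficult fraction equals `target_prevalence`
#' (default 18%). Predictors are drawn independently — the joint
#' distribution of the original cohort is unpublished.
#'
#' @param n Number of procedures to simulate.
#' @param seed Integer seed; all randomness in [simulate_cohort()] flows
#'   from it.
#' @param spine_grade_probs Probabilities of grades 1-4 (sum to 1).
#' @param p_junior Probability of performer experience <=12 months.
#' @param p_positioning Probability of positioning difficulty.
#' @param beta_grade,beta_junior,beta_positioning Latent log-odds effects:
#'   per spine-grade step above 1, for a junior performer, and for
#'   positioning difficulty.
#' @param intercept Latent intercept; `NULL` (default) calibrates it with
#'   [calibrate_intercept()] to hit `target_prevalence`.
#' @param target_prevalence Expected difficult fraction in (0, 1).
#' @return A `sim_config` list.
#' @export
simulation_config <- function(n = 300, seed = 1L,
                              spine_grade_probs = c(95, 148, 52, 5) / 300,
                              p_junior = 196 / 300,
                              p_positioning = 12 / 300,
                              beta_grade = 0.9,
                              beta_junior = 0.9,
                              beta_positioning = 2.7,
                              intercept = NULL,
                              target_prevalence = 0.18) {
  if (n < 1) abort("`n` must be >= 1.")
  if (abs(sum(spine_grade_probs) - 1) > 1e-8 || any(spine_grade_probs < 0)) {
    abort("`spine_grade_probs` must be non-negative and sum to 1.")
  }
  for (p in c(p_junior, p_positioning)) {
    if (p < 0 || p > 1) abort("Marginal probabilities must lie in [0, 1].")
  }
  cfg <- structure(
    list(n = as.integer(n), seed = as.integer(seed),
         spine_grade_probs = spine_grade_probs,
         p_junior = p_junior, p_positioning = p_positioning,
         beta_grade = beta_grade, beta_junior = beta_junior,
         beta_positioning = beta_positioning,
         intercept = intercept, target_prevalence = target_prevalence),
    class = "sim_config"
  )
  if (is.null(cfg$intercept)) cfg$intercept <- calibrate_intercept(cfg)
  cfg
}

# all 16 cells of the (grade, experience, positioning) lattice with their
# joint probabilities under independent marginals
predictor_lattice <- function(config) {
  tidyr::expand_grid(grade = 1:4, junior = c(0, 1), posdiff = c(0, 1)) |>
    dplyr::mutate(
      prob = config$spine_grade_probs[.data$grade] *
        ifelse(.data$junior == 1, config$p_junior, 1 - config$p_junior) *
        ifelse(.data$posdiff == 1, config$p_positioning, 1 - config$p_positioning)
    )
}

#' Calibrate the latent intercept to a target prevalence
#'
#' Finds the intercept at which the expected difficult fraction — the exact
#' expectation of the logistic difficulty probability over the 16-cell
#' predictor lattice — equals the configuration's target prevalence. The
#' expectation is strictly increasing in the intercept, so monotone
#' bisection converges; the result is within 1e-6 of the target by
#' construction (tolerance 1e-9 on the expectation).
#'
#' @param config A `sim_config` (its `intercept` field is ignored).
#' @return The calibrated intercept (log-odds scale).
#' @examples
#' # with no predictor effects the intercept is just logit(target)
#' cfg <- simulation_config(beta_grade = 0, beta_junior = 0,
#'                          beta_positioning = 0, target_prevalence = 0.18)
#' cfg$intercept  # ~ qlogis(0.18)
#' @export
calibrate_intercept <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  target <- config$target_prevalence
  if (target <= 0 || target >= 1) {
    abort("`target_prevalence` must be in (0, 1).")
  }
  lat <- predictor_lattice(config)
  lp0 <- config$beta_grade * (lat$grade - 1) +
    config$beta_junior * lat$junior +
    config$beta_positioning * lat$posdiff
  expect_prev <- function(a) sum(lat$prob * plogis(a + lp0))
  root <- stats::uniroot(function(a) expect_prev(a) - target,
                         lower = -50, upper = 50, tol = 1e-9)$root
  if (abs(expect_prev(root) - target) > 1e-6) {
    abort("Intercept calibration failed to reach the target prevalence.")
  }
  root
}

#' Simulate a synthetic procedure cohort
#'
#' Draws predictors independently from the configured marginals, difficulty
#' labels from the latent logistic model, puncture/pass outcome counts
#' consistent with the difficult-procedure definition (difficult: a handover
#' after the second puncture in ~15% of cases, otherwise >3 punctures or 3
#' punctures with >6 passes; easy: 1-3 punctures with at most 6 passes), and
#' demographics with index-cohort-like marginals. Fully reproducible: the
#' same configuration (including seed) always yields the identical cohort.
#'
#' @param config A `sim_config` from [simulation_config()].
#' @return A validated cohort tibble with predictor, demographic, outcome
#'   and `difficult` columns.
#' @examples
#' sim <- simulate_cohort(simulation_config(n = 300, seed = 42))
#' mean(sim$difficult)
#' @export
simulate_cohort <- function(config = simulation_config()) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n
  set.seed(config$seed)

  grade <- sample(1:4, n, replace = TRUE, prob = config$spine_grade_probs)
  junior <- runif(n) < config$p_junior
  posdiff <- runif(n) < config$p_positioning

  lp <- config$intercept + config$beta_grade * (grade - 1) +
    config$beta_junior * junior + config$beta_positioning * posdiff
  difficult <- runif(n) < plogis(lp)

  # outcome counts consistent with the difficulty definition
  punctures <- integer(n); passes <- integer(n); handover <- logical(n)
  n_diff <- sum(difficult)
  if (n_diff > 0) {
    mode <- sample(c("handover", "many_punctures", "many_passes"), n_diff,
                   replace = TRUE, prob = c(0.15, 0.55, 0.30))
    pu <- ifelse(mode == "handover", 2L,
                 ifelse(mode == "many_punctures",
                        sample(4:6, n_diff, replace = TRUE,
                               prob = c(0.6, 0.3, 0.1)), 3L))
    pa <- pu + sample(0:3, n_diff, replace = TRUE)
    pa[mode == "many_passes"] <- 7L + sample(0:3, sum(mode == "many_passes"),
                                             replace = TRUE)
    punctures[difficult] <- pu
    passes[difficult] <- pa
    handover[difficult] <- mode == "handover"
  }
  n_easy <- n - n_diff
  if (n_easy > 0) {
    pu <- sample(1:3, n_easy, replace = TRUE, prob = c(0.7, 0.2, 0.1))
    extra <- vapply(pu, function(k) sample.int(6L - k + 1L, 1L) - 1L, integer(1))
    punctures[!difficult] <- pu
    passes[!difficult] <- pu + extra
  }

  # demographics: index-cohort-like marginals; bmi derived so that
  # bmi = weight / (height/100)^2 holds exactly
  age <- round(pmin(pmax(rnorm(n, 45.3, 16.6), 18), 90), 1)
  sex <- sample(c("male", "female"), n, replace = TRUE, prob = c(227, 73) / 300)
  height <- round(pmin(pmax(rnorm(n, 161.8, 9.3), 140), 195), 1)
  bmi_lat <- pmin(pmax(rnorm(n, 23.8, 5.0), 15), 45)
  weight <- round(bmi_lat * (height / 100)^2, 1)
  bmi <- round(weight / (height / 100)^2, 2)
  asa <- sample(c("I", "II", "III", "IV"), n, replace = TRUE,
                prob = c(76, 169, 49, 6) / 300)
  urgency <- sample(c("elective", "emergency"), n, replace = TRUE,
                    prob = c(291, 9) / 300)
  tls <- sample(c("convex", "straight", "concave"), n, replace = TRUE,
                prob = c(152, 133, 15) / 300)
  deformity <- runif(n) < 7 / 300
  position <- sample(c("sitting", "lateral"), n, replace = TRUE,
                     prob = c(294, 6) / 300)

  cohort <- tibble(
    id = sprintf("sim%05d", seq_len(n)),
    age = age, sex = sex, height = height, weight = weight, bmi = bmi,
    asa_class = asa, urgency = urgency,
    spine_grade = as.integer(grade),
    tls_contour = tls,
    experience = ifelse(junior, "<=12 months", ">12 months"),
    positioning_difficulty = posdiff,
    spine_deformity = deformity,
    position = position,
    punctures = punctures, passes = passes,
    handover_declared_difficult = handover,
    difficult = difficult
  )
  validate_cohort(cohort)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config> n =", x$n, " seed =", x$seed,
      " target prevalence =", x$target_prevalence, "\n")
  cat("  spine grade probs:", paste(signif(x$spine_grade_probs, 3), collapse = " "),
      "\n  P(junior) =", signif(x$p_junior, 3),
      " P(positioning difficulty) =", signif(x$p_positioning, 3), "\n")
  cat("  latent: logit(p) =", signif(x$intercept, 4), "+",
      x$beta_grade, "* (grade-1) +", x$beta_junior, "* junior +",
      x$beta_positioning, "* posdiff\n")
  invisible(x)
}
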