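test_that("intercept calibration matches closed forms and the lattice expectation", {
  # no predictor effects: intercept is logit(target)
  cfg0 <- simulation_config(beta_grade = 0, beta_junior = 0,
                            beta_positioning = 0, target_prevalence = 0.5)
  expect_equal(cfg0$intercept, 0, tolerance = 1e-8)
  cfg18 <- simulation_config(beta_grade = 0, beta_junior = 0,
                             beta_positioning = 0, target_prevalence = 0.18)
  expect_equal(cfg18$intercept, qlogis(0.18), tolerance = 1e-8)

  # default coefficients: exact expectation over the 16 predictor cells
  cfg <- simulation_config()
  lat <- tidyr::expand_grid(grade = 1:4, junior = c(0, 1), posdiff = c(0, 1))
  prob <- cfg$spine_grade_probs[lat$grade] *
    ifelse(lat$junior == 1, cfg$p_junior, 1 - cfg$p_junior) *
    ifelse(lat$posdiff == 1, cfg$p_positioning, 1 - cfg$p_positioning)
  prev <- sum(prob * plogis(cfg$intercept + cfg$beta_grade * (lat$grade - 1) +
                              cfg$beta_junior * lat$junior +
                              cfg$beta_positioning * lat$posdiff))
  expect_equal(prev, 0.18, tolerance = 1e-6)

  expect_error(simulation_config(target_prevalence = 1.5), "target_prevalence")
  expect_error(simulation_config(spine_grade_probs = c(0.5, 0.5, 0.5, 0.5)),
               "sum to 1")
})

test_that("simulation is deterministic under a fixed seed", {
  a <- simulate_cohort(simulation_config(n = 200, seed = 99))
  b <- simulate_cohort(simulation_config(n = 200, seed = 99))
  expect_identical(a, b)
  c <- simulate_cohort(simulation_config(n = 200, seed = 100))
  expect_false(identical(a, c))
})

test_that("simulated outcome counts encode exactly the intended difficulty labels", {
  sim <- simulate_cohort(simulation_config(n = 2000, seed = 5))
  expect_identical(
    classify_difficult(sim$punctures, sim$passes,
                       sim$handover_declared_difficult),
    sim$difficult
  )
  easy <- dplyr::filter(sim, !difficult)
  expect_true(all(easy$punctures <= 3 & easy$passes <= 6))
  expect_true(all(sim$passes >= sim$punctures))
})

test_that("the difficult fraction at n = 300 centres on 18% over replicates", {
  fracs <- vapply(1:200, function(s) {
    mean(simulate_cohort(simulation_config(n = 300, seed = s))$difficult)
  }, numeric(1))
  expect_lt(abs(mean(fracs) - 0.18), 0.05)
})

test_that("a null positioning effect leaves difficulty independent of positioning", {
  sim <- simulate_cohort(simulation_config(n = 10000, seed = 21,
                                           beta_positioning = 0,
                                           p_positioning = 0.5))
  rate <- tapply(sim$difficult, sim$positioning_difficulty, mean)
  expect_lt(abs(rate[["TRUE"]] - rate[["FALSE"]]), 0.03)
})

test_that("a logistic refit on a large cohort recovers the latent coefficients", {
  cfg <- simulation_config(n = 100000, seed = 77)
  sim <- simulate_cohort(cfg)
  fit <- glm(difficult ~ I(spine_grade - 1) + I(experience == "<=12 months") +
               positioning_difficulty,
             family = binomial(), data = sim)
  est <- coef(fit)
  se <- sqrt(diag(vcov(fit)))
  truth <- c(cfg$intercept, cfg$beta_grade, cfg$beta_junior,
             cfg$beta_positioning)
  expect_true(all(abs(est - truth) <= 3 * se))
})

test_that("simulate -> score -> ROC -> diagnostics runs across random configurations", {
  set.seed(55)
  for (i in 1:25) {
    cfg <- simulation_config(
      n = sample(150:400, 1), seed = sample.int(1e6, 1),
      target_prevalence = runif(1, 0.08, 0.45),
      beta_grade = runif(1, 0.3, 1.4),
      beta_junior = runif(1, 0, 1.2),
      beta_positioning = runif(1, 0.5, 3)
    )
    sim <- simulate_cohort(cfg)
    if (!any(sim$difficult) || all(sim$difficult)) next
    res <- sim |> score_cohort() |> evaluate_scores()
    expect_s3_class(res$roc, "roc_curve")
    expect_true(res$roc$auc >= 0 && res$roc$auc <= 1)
    expect_true(all(res$report$statistics$estimate[
      res$report$statistics$statistic %in%
        c("sensitivity", "specificity", "ppv", "npv", "accuracy")] <= 1,
      na.rm = TRUE))
  }
})

test_that("large-sample sensitivity converges to its lattice expectation", {
  cfg <- simulation_config(n = 60000, seed = 31)
  sim <- simulate_cohort(cfg) |> score_cohort()
  roc <- roc_curve(sim$dsp_score, sim$difficult)

  # analytic sens/spec at cutoff 2 from the 16-cell lattice
  lat <- tidyr::expand_grid(grade = 1:4, junior = c(0, 1), posdiff = c(0, 1))
  prob <- cfg$spine_grade_probs[lat$grade] *
    ifelse(lat$junior == 1, cfg$p_junior, 1 - cfg$p_junior) *
    ifelse(lat$posdiff == 1, cfg$p_positioning, 1 - cfg$p_positioning)
  p_diff <- plogis(cfg$intercept + cfg$beta_grade * (lat$grade - 1) +
                     cfg$beta_junior * lat$junior +
                     cfg$beta_positioning * lat$posdiff)
  score <- (lat$grade - 1) + lat$junior + 3 * lat$posdiff
  sens_true <- sum(prob * p_diff * (score >= 2)) / sum(prob * p_diff)
  spec_true <- sum(prob * (1 - p_diff) * (score < 2)) / sum(prob * (1 - p_diff))

  at2 <- roc$points[roc$points$cutoff == 2, ]
  expect_lt(abs(at2$sensitivity - sens_true), 0.02)
  expect_lt(abs(at2$specificity - spec_true), 0.02)
})
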