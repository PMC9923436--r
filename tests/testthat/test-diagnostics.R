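index_counts <- function() confusion_counts(53, 107, 1, 139, cutoff = 2L)

test_that("2x2 construction respects the score >= cutoff positivity convention", {
  co <- index_cohort()
  cts <- build_two_by_two(co$dsp_score, co$difficult, cutoff = 2)
  expect_identical(c(cts$tp, cts$fp, cts$fn, cts$tn), c(53L, 107L, 1L, 139L))

  # cutoff 0: everyone positive
  cts0 <- build_two_by_two(co$dsp_score, co$difficult, cutoff = 0)
  expect_identical(cts0$fn, 0L)
  expect_identical(cts0$tn, 0L)

  # perfect separation
  cts2 <- build_two_by_two(c(0L, 7L), c(FALSE, TRUE), cutoff = 4)
  expect_identical(c(cts2$tp, cts2$fp, cts2$fn, cts2$tn), c(1L, 0L, 0L, 1L))

  expect_error(build_two_by_two(c(1, 2), c(TRUE, TRUE), 1), "Both outcome classes")
  expect_error(confusion_counts(-1, 0, 0, 2), "non-negative")
})

test_that("the index-cohort report reproduces the published statistics at printed precision", {
  rep <- diagnostic_report(index_counts(), prevalence = 0.18)
  est <- setNames(rep$statistics$estimate, rep$statistics$statistic)
  expect_equal(round(100 * est[["sensitivity"]], 2), 98.15)
  expect_equal(round(100 * est[["specificity"]], 2), 56.50)
  expect_equal(round(est[["plr"]], 2), 2.26)
  expect_equal(round(est[["nlr"]], 2), 0.03)
  expect_equal(round(100 * est[["ppv"]], 2), 33.12)
  expect_equal(round(100 * est[["npv"]], 2), 99.29)
  expect_equal(round(100 * est[["accuracy"]], 2), 64.00)
})

test_that("confidence intervals reproduce the published bounds by their stated methods", {
  rep <- diagnostic_report(index_counts(), prevalence = 0.18)
  s <- rep$statistics
  ci <- function(stat) {
    r <- s[s$statistic == stat, ]
    c(lower = r$lower, upper = r$upper)
  }

  # Clopper-Pearson for sensitivity 53/54 and specificity 139/246
  expect_equal(round(100 * ci("sensitivity"), 2),
               c(lower = 90.11, upper = 99.95))
  expect_equal(round(100 * ci("specificity"), 2),
               c(lower = 50.06, upper = 62.79))
  # binom.test as an independent Clopper-Pearson oracle
  expect_equal(unname(ci("sensitivity")),
               as.numeric(binom.test(53, 54)$conf.int), tolerance = 1e-10)

  # Simel log method, recomputed independently from its closed form
  z <- qnorm(0.975)
  se_plr <- sqrt(1 / 53 - 1 / 54 + 1 / 107 - 1 / 246)
  expect_equal(unname(ci("plr")),
               exp(log((53 / 54) / (107 / 246)) + c(-1, 1) * z * se_plr),
               tolerance = 1e-12)
  expect_equal(round(ci("plr"), 2), c(lower = 1.95, upper = 2.61))
  expect_equal(round(ci("nlr"), 2), c(lower = 0.00, upper = 0.23))

  # Mercaldo logit intervals for the prevalence-adjusted predictive values
  expect_equal(round(100 * ci("ppv"), 2), c(lower = 29.95, upper = 36.46))
  expect_equal(round(100 * ci("npv"), 2), c(lower = 95.21, upper = 99.90))

  # accuracy: Clopper-Pearson on the implied 192/300 correct calls
  expect_equal(round(100 * ci("accuracy"), 2),
               c(lower = 58.28, upper = 69.44))
})

test_that("prevalence-consistency identities hold exactly on random counts", {
  set.seed(101)
  for (i in 1:50) {
    cts <- random_counts()
    total <- cts$tp + cts$fp + cts$fn + cts$tn
    p_own <- (cts$tp + cts$fn) / total
    if (p_own <= 0 || p_own >= 1) next
    rep <- diagnostic_report(cts, prevalence = p_own)
    est <- setNames(rep$statistics$estimate, rep$statistics$statistic)
    if (cts$tp + cts$fp > 0) {
      expect_equal(est[["ppv"]], cts$tp / (cts$tp + cts$fp), tolerance = 1e-12)
    }
    if (cts$tn + cts$fn > 0) {
      expect_equal(est[["npv"]], cts$tn / (cts$tn + cts$fn), tolerance = 1e-12)
    }
    expect_equal(est[["accuracy"]], (cts$tp + cts$tn) / total, tolerance = 1e-12)
    # accuracy identity from the report's own fields
    expect_equal(est[["accuracy"]],
                 rep$prevalence * est[["sensitivity"]] +
                   (1 - rep$prevalence) * est[["specificity"]],
                 tolerance = 1e-12)
  }
})

test_that("PLR > 1 iff NLR < 1 iff Youden J positive, over random counts", {
  set.seed(202)
  for (i in 1:50) {
    cts <- random_counts()
    rep <- diagnostic_report(cts)
    est <- setNames(rep$statistics$estimate, rep$statistics$statistic)
    j <- est[["sensitivity"]] + est[["specificity"]] - 1
    if (abs(j) < 1e-12 || !is.finite(est[["plr"]])) next
    expect_identical(j > 0, est[["plr"]] > 1)
    expect_identical(j > 0, est[["nlr"]] < 1)
  }
})

test_that("increasing tp with tn fixed never decreases sensitivity", {
  sens_of <- function(tp) {
    rep <- diagnostic_report(confusion_counts(tp, 10, 5, 20))
    rep$statistics$estimate[rep$statistics$statistic == "sensitivity"]
  }
  s <- vapply(1:30, sens_of, numeric(1))
  expect_true(all(diff(s) >= 0))
})

test_that("Clopper-Pearson intervals contain the point estimate and cover at n = 54", {
  set.seed(303)
  for (x in c(0, 1, 27, 53, 54)) {
    ci <- diagnostic_report(confusion_counts(max(x, 1), 10,
                                             54 - max(x, 1), 10))$statistics
    lo <- ci$lower[ci$statistic == "sensitivity"]
    hi <- ci$upper[ci$statistic == "sensitivity"]
    expect_true(lo <= max(x, 1) / 54 && max(x, 1) / 54 <= hi)
  }
  # empirical coverage of the exact interval at n = 54 is >= the nominal 95%
  p_true <- 0.9
  draws <- rbinom(2000, 54, p_true)
  covered <- vapply(draws, function(x) {
    lo <- if (x == 0) 0 else qbeta(0.025, x, 54 - x + 1)
    hi <- if (x == 54) 1 else qbeta(0.975, x + 1, 54 - x)
    lo <= p_true && p_true <= hi
  }, logical(1))
  expect_gte(mean(covered), 0.95)
})

test_that("degenerate cells are flagged rather than silently patched", {
  # perfect test: PLR unbounded, NLR zero
  rep <- diagnostic_report(confusion_counts(10, 0, 0, 10), prevalence = 0.5)
  est <- setNames(rep$statistics$estimate, rep$statistics$statistic)
  expect_identical(est[["plr"]], Inf)
  expect_identical(est[["nlr"]], 0)
  expect_equal(est[["sensitivity"]], 1)
  expect_equal(est[["accuracy"]], 1)
  notes <- rep$statistics$note
  expect_match(notes[rep$statistics$statistic == "plr"], "unbounded")
  expect_match(notes[rep$statistics$statistic == "nlr"], "zero cell")

  expect_error(diagnostic_report(index_counts(), prevalence = 1.2), "prevalence")
  expect_error(diagnostic_report(confusion_counts(1, 0, 0, 0)), "Both condition")
})

test_that("the report round-trips to JSON with full precision", {
  rep <- diagnostic_report(index_counts(), prevalence = 0.18)
  path <- withr::local_tempfile(fileext = ".json")
  write_diagnostic_report(rep, path)
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(doc$prevalence, 0.18)
  expect_equal(doc$counts$tp, 53)
  got <- setNames(doc$statistics$estimate, doc$statistics$statistic)
  expect_equal(got[["sensitivity"]], 53 / 54, tolerance = 1e-12)
})
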