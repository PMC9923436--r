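---
title: "The DSP Score: construction, evaluation and simulation methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The DSP Score: construction, evaluation and simulation methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dspscore)
```

## The problem and the model

Difficult spinal-arachnoid punctures — procedures needing repeated skin
punctures and needle passes — cause patient discomfort, trauma and
occasional failure, so predicting them before positioning the patient has
real clinical value. The DSP Score is a three-item additive integer score
for exactly that purpose. A procedure is *difficult* when any of three
clauses holds: more than 3 punctures; exactly 3 punctures with more than 6
passes; or a handover after the second puncture with the performer deeming
it difficult (`classify_difficult()` implements the disjunction literally;
`passes >= punctures` is enforced because a pass is a needle movement
within a puncture).

### From coefficients to points

The score is not hand-assigned: `build_score_model()` converts a coefficient
table into integer weights by a fixed three-step rule.

1. **Filter.** Keep predictors with `p_value` below the significance
   threshold (default 0.01, the value used for the shipped model).
2. **Magnitude.** A predictor's maximum weight is |estimate| rounded to the
   nearest integer. We round half away from zero; base R's `round()` rounds
   half to even, and the two disagree only at exact .5, which does not occur
   in the shipped coefficients (2.715 → 3, 2.98 → 3, 1.045 → 1) — the
   choice is documented because a user-supplied table could hit it.
3. **Direction.** A negative estimate means the score rises with the level
   order the caller supplies (weights 0..max ascending); a positive estimate
   the reverse. The level order is therefore part of the model definition —
   nothing about reference levels is inferred from data. For ordinal
   predictors the ladder is the linear integer sequence 0..max, which is
   only well defined when max equals the number of levels minus one (true
   for spine grade: 3 = 4 − 1). Any other combination is rejected with an
   error rather than silently interpolated: there is no principled way to
   spread, say, 5 points over 3 levels, and guessing would change scores
   silently. A rounded weight of 0 for a retained predictor is likewise an
   error — a "significant" predictor carrying no points signals a unit or
   coding problem upstream.

The shipped coefficient table (`dsp_coefficients()`) yields spine grade
0/1/2/3, experience ≤ 12 months 1, positioning difficulty present 3, hence
an aggregate range of 0–7; all 16 predictor combinations are realizable and
cover every integer in that range. Models serialize to JSON
(`write_score_model()`) so other scores can be defined without touching
code.

## Diagnostic evaluation

`evaluate_scores()` chains the evaluation stages; each is also exposed on
its own.

**ROC.** For an integer score, every distinct observed value is a candidate
cutoff, plus one above the maximum (the all-negative point). Positivity is
`score >= cutoff` throughout. The published 2×2 table labels its rows
">2"/"<2", but its counts partition all 300 records and give sensitivity
53/54 at cutoff 2 — only consistent with a ≥2 vs <2 split — so the package
treats those labels as typographical shorthand and says so in the
`build_two_by_two()` documentation. The AUC is the trapezoid rule over the
ROC vertices with (0,0)/(1,1) anchors; for discrete scores this equals the
Mann–Whitney statistic with half credit for ties, and the test suite
asserts that identity against a brute-force pairwise oracle. The AUC
interval uses the Hanley–McNeil variance — a documented choice; the
published interval (0.811–0.905) was produced by an unnamed online
calculator and is reported for comparison, not asserted.

**Cutoff selection.** `youden_cutoff()` maximizes J = sens + spec − 1;
`efficiency_cutoff()` maximizes eff(c; P) = P·sens + (1−P)·spec, the
expected proportion correctly classified at prevalence P. At P = 0.5,
eff = J/2 + 1/2, so the two agree — property-tested on random cohorts. Ties
break toward the smaller cutoff; the published grid has no ties, so this is
a repository convention, chosen because a smaller cutoff favors sensitivity
in a screening context.

**2×2 statistics.** `diagnostic_report()` computes sensitivity,
specificity, PLR, NLR, prevalence-adjusted PPV/NPV and accuracy
`p·sens + (1−p)·spec`. When `prevalence` is the cohort's own, the adjusted
values reduce exactly to tp/(tp+fp), tn/(tn+fn) and (tp+tn)/total —
identities the tests verify on random tables. Interval methods:

- *Clopper–Pearson* (exact beta quantiles, z-free) for sensitivity,
  specificity and accuracy. For accuracy at an external prevalence the
  interval is CP on the implied number of correct calls
  `round(acc · total)` at the cohort size — this exactly reproduces the
  published accuracy interval, which is how the choice was settled.
- *Simel log method* for likelihood ratios:
  `exp(log(LR) ± z·se)` with `se² = 1/tp − 1/n₁ + 1/fp − 1/n₀` (PLR) and
  the fn/tn analogue (NLR).
- *Mercaldo logit method* for prevalence-adjusted PPV/NPV, i.e. a normal
  interval on the logit scale with variance
  `(1−sens)/(n₁·sens) + spec/(n₀·(1−spec))` for PPV (prevalence treated as
  fixed).

The z-quantile is `qnorm(0.975)` = 1.959964, not a rounded 1.96. Zero cells
are never continuity-corrected: specificity 1 makes the PLR unbounded and a
zero fn makes the NLR 0, and the affected endpoints propagate as 0/`Inf`
with an explanatory note instead of a 0.5 substitution.

## Reconstructing the index cohort

The original per-procedure data are unpublished, but the grouped score
distribution is identifiable from the printed per-cutoff operating points:
with 54 difficult and 246 easy procedures, `round(54·sens(c))` and
`round(246·spec(c))` at cutoffs 2, 3, 4 invert uniquely to bins
(<2, =2, =3, ≥4) = (1, 27, 24, 2) difficult and (139, 99, 8, 0) easy.
`reconstruct_distribution()` performs the inversion and *verifies* it —
recomputed operating points must reproduce every printed 3-decimal value,
and negative implied counts are rejected with the offending cutoff — so a
mistyped input cannot silently produce a cohort.

`expand_to_cohort()` turns bins into records by placing each bin at one
concrete score and assigning a fixed predictor combination realizing it
(common levels preferred: positioning difficulty is rare, junior performers
common). Two caveats are inherent, not implementation gaps:

- the <2 bin's internal 0-vs-1 composition is unidentifiable; the default
  puts all 140 records at score 1, and `bin_scores` exposes the choice.
  This is also why the reconstructed AUC (0.8626) cannot equal the
  published 0.858 exactly: moving easy records from 1 to 0 changes only
  tie credit at the third decimal. The package asserts |AUC − 0.858| < 0.01
  rather than equality.
- the joint distribution of all baseline covariates is not recoverable from
  marginals, so the expansion makes no attempt to also match the cohort-
  characteristics table; only scores, group sizes and outcomes are faithful.

## The synthetic-cohort generator

`simulate_cohort()` exists so every stage is testable end to end without
external data. Its defaults emulate the index cohort:

- **Predictor marginals** from the pooled published counts: spine grades
  95/148/52/5 of 300, experience ≤ 12 months 196/300, positioning
  difficulty 12/300. Predictors are drawn independently — the true joint
  distribution is unpublished; this is a deliberate simplification, so
  simulated cohorts will not reproduce, e.g., any grade-experience
  correlation a real service might have.
- **Latent difficulty model**: logistic in (spine grade − 1), junior
  experience, positioning difficulty with coefficients 0.9 / 0.9 / 2.7 —
  signs matching the reported estimates, magnitudes proportional to the
  integer weights (0.9 per point), which gives discrimination of the same
  order as the index cohort (AUC ≈ 0.8).
- **Intercept calibration**: `calibrate_intercept()` solves for the
  intercept at which the *exact* expectation of the difficulty probability
  over the 16-cell predictor lattice equals the target prevalence (default
  0.18). The expectation is strictly monotone in the intercept, so
  root-finding with tolerance 1e−9 lands within 1e−6 of the target by
  construction; no Monte-Carlo is involved in the calibration itself.
- **Outcome counts** are drawn to satisfy the difficulty definition by
  construction (difficult: 15% handovers, 55% >3 punctures, 30% three
  punctures with 7–10 passes; easy: 1–3 punctures, ≤ 6 passes). Any
  distribution on the correct side of the definition would do; these
  defaults are documented, and the tests assert only the classifier
  round-trip, not the arbitrary proportions.
- **Demographics** (age, sex, BMI and friends) are generated with
  index-cohort-like marginals purely for realism; BMI is derived from the
  generated height and weight so the internal consistency check holds.

All randomness flows from the single seed in `simulation_config()`; the
same configuration always reproduces the identical cohort.

What passing simulation tests shows — and what it does not: the pipeline is
exercised on cohorts with realistic marginals, prevalence and effect
directions, and a logistic refit at n = 10⁵ recovers the latent
coefficients within 3 standard errors. Real data could still differ in
ways the generator does not emulate (correlated predictors, per-performer
clustering, secular trends), so these tests validate the *software*, not
the score's external validity.

## Problem sizes and numerical conventions

The test suite exercises property checks on dozens of random cohorts of
n ≈ 20–400, Monte-Carlo prevalence checks over 200 replicates of n = 300,
and one large n = 10⁵ cohort for coefficient recovery — sizes chosen to
make sampling error negligible relative to the asserted tolerances while
staying cheap enough to re-run on every change. Percentages print to 2
decimals and ratios to 2 decimals, matching the conventional reporting
style; JSON outputs carry full precision. Known limitations: no partial or
smoothed ROC, no bootstrap or Bayesian intervals, no multi-class outcomes,
and the score builder deliberately refuses ordinal predictors whose rounded
weight does not match their level count.
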