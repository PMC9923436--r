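# dspscore

Anesthesiologists planning a spinal-arachnoid puncture (spinal anesthesia,
diagnostic lumbar puncture, lumbar drainage) want to know in advance which
patients are likely to need repeated punctures and needle passes. `dspscore`
implements the **Difficult Spinal-arachnoid Puncture (DSP) Score** — an
additive integer bedside score over spine grade, performer experience and
positioning difficulty — together with the full machinery to build such
scores from model coefficients and to evaluate them as diagnostic tests.

A procedure counts as *difficult* when it needed more than 3 punctures,
exactly 3 punctures with more than 6 passes, or a handover after the second
puncture with the performer deeming it difficult. The DSP Score assigns

| Predictor | Levels | Points |
|---|---|---|
| Spine grade | 1 / 2 / 3 / 4 | 0 / 1 / 2 / 3 |
| Performer experience | ≤ 12 months / > 12 months | 1 / 0 |
| Positioning difficulty | absent / present | 0 / 3 |

so the aggregate ranges 0–7. The weights are not hard-coded: they are built
mechanically from the underlying model's coefficient table by
`build_score_model()` — keep predictors with Pr(>|z|) < 0.01, set each
predictor's maximum weight to |estimate| rounded to the nearest integer, and
orient the weights by the coefficient sign (negative ⇒ points rise with the
level). Evaluation follows the standard diagnostic-test toolkit:

- discrete-score ROC curve, trapezoidal AUC (= the tied-rank Mann–Whitney
  statistic) with a Hanley–McNeil confidence interval;
- Youden's J cutoff, `J(c) = sens(c) + spec(c) − 1`, and prevalence-weighted
  efficiency cutoffs, `eff(c; P) = P·sens(c) + (1−P)·spec(c)`;
- 2×2 statistics with Clopper–Pearson (sensitivity, specificity, accuracy),
  Simel log-method (likelihood ratios) and Mercaldo logit
  (prevalence-adjusted PPV/NPV) confidence intervals.

Because the original per-patient data are not deposited, the package also
rebuilds the 300-procedure index cohort from the published grouped
operating points (`reconstruct_distribution()`, `index_cohort()`) and ships
a seeded synthetic-cohort generator (`simulate_cohort()`) with a calibrated
logistic latent difficulty model.

## Worked example

```r
library(dspscore)

index_cohort() |> evaluate_scores(prevalence = 0.18)
```

```
AUC 0.863 (95% CI 0.798-0.927)
Youden cutoff 2 (J = 0.547, sens 0.981, spec 0.565)
Efficiency-optimal cutoffs:
  P = 0.01 -> cutoff 4 (eff 0.990, sens 0.037, spec 1.000)
  P = 0.05 -> cutoff 4 (eff 0.952, sens 0.037, spec 1.000)
  P = 0.1  -> cutoff 3 (eff 0.919, sens 0.481, spec 0.967)
  P = 0.2  -> cutoff 3 (eff 0.870, sens 0.481, spec 0.967)
  P = 0.3  -> cutoff 3 (eff 0.822, sens 0.481, spec 0.967)
  P = 0.5  -> cutoff 2 (eff 0.773, sens 0.981, spec 0.565)

Diagnostic report (score >=2, 300 records)
              Condition +  Condition -
  test +        53 (17.67%)   107 (35.67%)
  test -         1 (0.33%)   139 (46.33%)
  Prevalence used: 18.00%
  sensitivity    98.15%  95% CI 90.11%-99.95%
  specificity    56.50%  95% CI 50.06%-62.79%
  plr              2.26  95% CI 1.95-2.61
  nlr              0.03  95% CI 0.00-0.23
  ppv            33.12%  95% CI 29.95%-36.46%
  npv            99.29%  95% CI 95.21%-99.90%
  accuracy       64.00%  95% CI 58.28%-69.44%
```

Reading: at the Youden-optimal cutoff of 2 the score misses almost no
difficult procedure (sensitivity 98.15%) at the price of flagging many easy
ones (specificity 56.50%); at an 18% difficulty prevalence a score below 2
virtually rules difficulty out (NPV 99.29%), which is what one wants from a
screening tool. In a low-prevalence setting a higher cutoff classifies a
larger share correctly — hence cutoff 3 or 4 maximizes efficiency at small P.

Tidy accessors (`tidy()`, `glance()`) and plots (`autoplot()` on ROC curves,
score distributions and diagnostic reports) are available on every result
object. A thin command-line front end wraps the same functions:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli", "dsp.R", package = "dspscore"))')" \
  reconstruct --out index.csv
```

with subcommands `score`, `evaluate`, `reconstruct`, `simulate`.

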