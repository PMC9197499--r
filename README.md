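# polycat

Computerized adaptive testing (CAT) for polytomous questionnaire item
banks, in R.

Severity constructs measured with Likert batteries — the motivating case
is problematic mobile phone use, assessed with seven overlapping Chinese
instruments totalling 98 items — are usually scored with long fixed forms.
`polycat` implements the alternative: calibrate all items onto one latent
severity scale with polytomous item response theory, screen the bank, and
then administer items adaptively, stopping as soon as a precision target
is reached. An evaluation harness quantifies what adaptivity buys over
fixed short forms of the same length.

## What is inside

* **Response models.** Graded response model (GRM) with cumulative
  logistic curves `P(X ≥ t) = 1 / (1 + exp[−D a(θ − b_t)])`, and the
  generalized partial credit model (GPCM) softmax over cumulative step
  sums (log-sum-exp safe). Fisher information in closed form for both,
  test information, `SE(θ) = 1/√ΣI(θ)`, and marginal reliability
  `MR = 1 − (mean SE)²`.
* **Calibration.** `fit_irt()` — Bock–Aitkin marginal maximum likelihood
  EM on a 61-node quadrature grid with a standard-normal prior, monotone
  threshold reparameterisation, honest convergence reporting, and
  `print`/`summary`/`coef`/`logLik`/`predict`/`plot`/`simulate` methods.
  `fit_indices()` and `select_model()` handle AIC/BIC model choice.
* **Screening.** First-principal-component loading filter (< 0.4 drops),
  KMO sampling adequacy, eigenvalue-ratio and variance-share
  unidimensionality checks, discrimination filter (< 0.8 drops), and an
  ordinal logistic-regression DIF scan (McFadden ΔR² > 0.02 flags),
  wired in fixed order by `build_item_bank()`.
* **Adaptive engine.** EAP scoring on a prior grid, maximum-information
  selection, SE-target / fixed-length / whole-bank stop rules, post-hoc
  (real-data) replay per respondent (`run_cat_posthoc()`) and cohort
  aggregation (`simulate_cohort()`).
* **Evaluation.** Equal-length CAT-versus-fixed-form comparisons (percent
  change, paired *t*, Cohen's *d* = t/√n), estimate correlation tables,
  and equal-accuracy length tables.
* **Synthetic data.** `synth_spec()` / `generate_dataset()` generate item
  banks and cohorts with the battery's structure (98 items across 7
  scales, discriminations ~ truncated normal 1.26 ± 0.31 on [0.87, 2.36],
  thresholds on [−2.4, 3.6]), plus planted weak items and planted DIF for
  power experiments.

## Worked example

```r
library(polycat)

# a synthetic cohort with the default 7-scale, 98-item structure
spec <- synth_spec(n_respondents = 300, seed = 42)
dat  <- generate_dataset(spec)

# calibrate the bank
fit <- fit_irt(dat$responses, model = "GRM", tol = 1e-3)
fit
#> <irt_fit: GRM, 98 items, N = 300>
#>   logLik -32763.85 on 491 item parameters; converged in 54 EM iterations

# replay every respondent adaptively, stopping at SE <= 0.4
simulate_cohort(dat$responses, fit$bank, stop_rule("se", se_target = 0.4))
#> SE(theta) = 0.4    items used 6.98 (SD 0.51)  mean SE 0.39  MR 0.85  r(full) 0.94

# compare CAT with two fixed scales at equal length
scales <- split(dat$bank$item_id, dat$bank$scale_id)[c("S1", "S2")]
compare_same_length(dat$responses, fit$bank, scales)
#> Measurement error at equal test length (fixed form vs CAT):
#>  scale length pp_mean pp_sd cat_mean cat_sd pct_change      t     d
#>     S1     16    0.35  0.01     0.27   0.01       23.3 179.26 10.35
#>     S2     10    0.53  0.04     0.33   0.01       37.7 100.27  5.79
#>
#> Measurement reliability at equal test length:
#>  scale length pp_mean pp_sd cat_mean cat_sd pct_change      t    d
#>     S1     16    0.87  0.01     0.93   0.00        5.9 152.54 8.81
#>     S2     10    0.72  0.04     0.89   0.01       24.4  73.68 4.25
```

Reading the output: with an SE ≤ 0.4 stop rule the adaptive test needs
about 7 of the 98 items per person while keeping marginal reliability at
0.85 and correlating 0.94 with the estimate from the entire bank. At equal
test length, the adaptive test cuts measurement error by 23–38% relative
to fixed scales and lifts reliability accordingly; `t` and `d` are the
paired test and effect size over the 300 per-person differences.

A thin command-line wrapper over the same functions ships in
`inst/cli/polycat.R` (subcommands `synth`, `calibrate`, `screen`,
`simulate-cat`, `evaluate`); run it with
`Rscript $(Rscript -e 'cat(system.file("cli/polycat.R", package = "polycat"))') <command> ...`.

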