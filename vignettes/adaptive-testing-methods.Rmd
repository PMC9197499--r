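---
title: "Methods: polytomous IRT calibration and adaptive-test simulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: polytomous IRT calibration and adaptive-test simulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polycat)
```

## The measurement problem

Severity constructs such as problematic mobile phone use are usually
measured with fixed Likert questionnaires scored by summing items. Fixed
forms spend most of their items far from any one respondent's severity
level, so they are long, and their precision is uneven across the severity
range. Computerized adaptive testing (CAT) instead selects, at each step,
the single unanswered item that is most informative at the respondent's
current severity estimate, and stops as soon as a precision target is met.
`polycat` implements the full workflow: item-bank screening, polytomous
item response theory (IRT) calibration, the adaptive loop, and an
evaluation harness that quantifies what adaptivity buys over fixed short
forms.

## Response models

Let $\theta$ denote the latent severity, scaled to a standard-normal
population prior, and let item $j$ have $m_j$ ordered categories scored
$0,\dots,m_j-1$.

**Graded response model (GRM).** Cumulative category probabilities are
logistic in $\theta$ with discrimination $a_j > 0$ and ordered thresholds
$b_{j1} \le \dots \le b_{j,m_j-1}$:

$$P(X_{j} \ge t \mid \theta) = \frac{1}{1 + \exp[-D a_j(\theta - b_{jt})]},
\qquad P(X_j = t) = P(X_j \ge t) - P(X_j \ge t+1),$$

with $P(X_j \ge 0) = 1$ and $P(X_j \ge m_j) = 0$.

**Generalized partial credit model (GPCM).** Category probabilities are a
softmax over cumulative step sums with step parameters $\delta_{jv}$
($\delta_{j0} \equiv 0$):

$$P(X_j = t \mid \theta) =
  \frac{\exp \sum_{v=0}^{t} D a_j (\theta - \delta_{jv})}
       {\sum_{h=0}^{m_j-1} \exp \sum_{v=0}^{h} D a_j (\theta - \delta_{jv})}.$$

The scaling constant $D$ defaults to 1 (the logistic metric); $D = 1.7$
gives the normal-ogive metric. For $m_j = 2$ the two models coincide
exactly, which the test suite asserts to machine precision. The GPCM
softmax is evaluated with log-sum-exp shifting, so arguments up to a few
hundred in magnitude neither overflow nor underflow.

**Information.** Fisher information is
$I_j(\theta) = \sum_t P_t'(\theta)^2 / P_t(\theta)$. For the GRM the
category derivatives are differences of cumulative-curve derivatives
$D a_j P^*(1-P^*)$; for the GPCM the sum collapses to
$(D a_j)^2\,\mathrm{Var}(T \mid \theta)$. Both closed forms are verified
against central finite differences ($h = 10^{-5}$, tolerance $10^{-6}$)
rather than trusted algebraically. Test information is the sum over
administered items, the standard error is
$SE(\theta) = 1/\sqrt{\sum_j I_j(\theta)}$, and the cohort-level marginal
reliability is $MR = 1 - \overline{SE}^2$ with $\overline{SE}$ the mean of
per-person standard errors.

## Calibration

`fit_irt()` maximizes the marginal likelihood with the Bock–Aitkin EM
algorithm. The latent trait is integrated over a fixed equally spaced grid
(default 61 nodes on $[-4, 4]$) with standard-normal weights normalized to
sum to one; fixing the prior at mean 0, SD 1 also identifies the latent
scale, and no rescaling is applied after the fit. The E-step forms
posterior node weights per respondent; the M-step updates each item by
BFGS on its expected complete-data log-likelihood. Positivity of $a_j$ and
the GRM threshold ordering are enforced structurally — the optimizer works
on $\log a_j$ and on (first threshold, log gaps) — so no post-hoc sorting
can be needed. Because each M-step starts from the current parameters and
only accepts improvements, the marginal log-likelihood is nondecreasing
across iterations (a generalized EM argument); the suite asserts the trace
numerically. Convergence is declared when the log-likelihood improves by
less than `tol` (default $10^{-4}$); the `converged` flag reports what
actually happened, and non-convergence returns the current estimates
rather than failing.

Degenerate inputs are handled explicitly: items with no response variance
are excluded and reported; items whose data skip a category are collapsed
onto the observed categories with a warning, so thresholds always refer to
categories that exist in the data.

Model choice between GRM and GPCM uses $AIC = -2LL + 2p$ and
$BIC = -2LL + p\ln N$ with $p = \sum_j m_j$ free item parameters. When the
two criteria disagree, AIC decides and a warning is emitted; an exact tie
defaults to the GRM. `fit_indices()` is exposed separately so deviances
reported elsewhere can be converted to information criteria without
refitting.

## Bank screening

The pipeline driver `build_item_bank()` fixes the stage order:

1. **Loading filter.** First-principal-component loadings of the item
   Pearson correlation matrix (pairwise-complete observations); items with
   loading strictly below 0.4 are dropped. Pearson correlations on the raw
   integer codes are the default deliberately — they match what standard
   statistics software computes in this situation; polychoric correlation
   is a known refinement we do not implement.
2. **Unidimensionality.** KMO sampling adequacy (anti-image formula, with
   a ridge-regularized inverse and a warning if the correlation matrix is
   singular), plus the two conventional eigenvalue rules: first/second
   eigenvalue ratio above 4 and first-component variance share above 20%.
3. **Calibration and model choice** as above.
4. **Discrimination filter.** Calibrated items with $a_j$ strictly below
   0.8 are dropped.
5. **DIF scan.** For each item, nested proportional-odds logistic
   regressions on the trait anchor: `item ~ trait` versus
   `item ~ trait + group + trait:group`, covering uniform and non-uniform
   differential item functioning jointly. The effect size is the change in
   McFadden's pseudo-$R^2$ (log-likelihood ratios against the
   intercept-only fit); items are flagged strictly above 0.02. The anchor
   is the full-bank EAP score, in a single pass without purification.
   Dichotomous or collapsed-to-two items use binomial logistic regression;
   a failed proportional-odds fit falls back to a median dichotomization
   with a warning.
6. **Final recalibration** of the retained items.

A boundary note on the DIF effect size: with the 0.02 cutoff, a uniform
threshold shift of 0.75 on an item of average discrimination
($a \approx 1.3$, $D = 1$) produces a population $\Delta R^2$ of roughly
0.02–0.03 — right at the decision boundary — while the same shift on a
highly discriminating item ($a \approx 2$) produces $\Delta R^2 \approx
0.05$ and is flagged reliably. Planted-DIF effects separate from null
items by an order of magnitude long before they cross the absolute cutoff,
so ranking by $\Delta R^2$ is informative even when flags are borderline.

## The adaptive loop

Severity is estimated by expected a posteriori (EAP): the posterior mean
over the prior grid, with posterior SD returned alongside. The reported
standard error is the information-based $1/\sqrt{\sum I_j(\hat\theta)}$
evaluated at the current estimate over the administered items — the same
quantity the stop rule monitors — rather than the posterior SD; both are
kept in the output so the two conventions can be compared.

The loop starts at the prior mean (0), selects by maximum information,
reads the respondent's recorded answer (post-hoc, real-data simulation),
re-estimates, and checks the stop rule; at least one item is administered
before any check, and the SE after zero items is infinite. Ties in
information break to the lowest bank position. Three rules are provided:
an SE target ($SE \le$ target), a fixed length, and "all" (administer the
entire bank, which reproduces the full-pattern EAP estimate exactly). In
post-hoc mode a missing recorded answer makes that item unavailable for
that respondent — selection recomputes with the remainder, preserving
adaptivity without imputation. The loop contains no randomness: identical
inputs give identical trajectories.

**Numerical accuracy of EAP.** With the default 61-node grid the EAP
estimate matches a 10,001-point trapezoid oracle to better than $10^{-4}$
for response patterns whose posterior lies in the well-populated range
(roughly $|\theta| < 2$); for extreme all-top/all-bottom patterns the
rectangular rule leaves a discretization error of order $10^{-3}$, which
vanishes as the grid is refined (the suite demonstrates recovery at 801
nodes). Users needing tail accuracy can pass a denser `prior_grid()`; the
61-node default balances speed in cohort loops against accuracy where
respondents actually live.

## Evaluation harness

`compare_same_length()` scores each fixed scale twice: as a fixed form
(EAP over the scale's items only) and as a fixed-length adaptive test of
the same length over the whole bank. Per person, the error arm compares
information-based SEs and the reliability arm compares $1 - SE^2$; each
arm reports means, SDs, the percent change of the cohort means, the paired
$t$ statistic, and Cohen's $d$ computed as $t/\sqrt{n}$ — the standardized
mean of the paired differences, the convention that reproduces reported
$(t, d)$ pairs in this literature. Reports round SE and reliability to two
decimals and percents to one. `equal_accuracy_table()` inverts the
comparison: each fixed scale's achieved mean SE becomes the adaptive stop
target, and the mean adaptive length is reported next to the fixed length.
Respondents who exhaust the bank before an aggressive target are counted,
not silently dropped. `estimate_correlations()` assembles the
means/SDs/correlation table of any named collection of aligned estimate
vectors.

## The synthetic-data generator

No respondent-level data ships with the package; every test builds its own
data through `synth_spec()` and `generate_dataset()`. The defaults encode
the study conditions the toolkit targets: a seven-scale battery of 98
items (16 items with 7 categories; 10 and 20 with 4; 11, 16, 11 and 14
with 5), discriminations from a truncated normal with mean 1.26 and SD
0.31 on $[0.87, 2.36]$, thresholds drawn uniformly over $[-2.4, 3.6]$ and
sorted with a minimum gap of 0.2 (avoiding near-degenerate categories),
and $\theta \sim N(0,1)$. Planted structure is available for power
studies: `weak_items` attenuates discriminations (producing low-loading
items the screening stage must catch), and `inject_dif()` builds
reference/focal bank pairs with shifted thresholds and/or scaled
discriminations. All randomness flows through explicit integer seeds, with
fixed offsets (+1 traits, +2 responses) so each component is independently
reproducible.

What the generator deliberately does **not** emulate: residual
correlations among items of the same scale beyond the single common factor
(real batteries are not exactly unidimensional), response styles such as
acquiescence or careless responding, and item-parameter drift. Passing
tests therefore certify the algorithms under a correctly specified
unidimensional model, not robustness to these real-data violations.

## Problem sizes and runtime choices

The test suite runs everything at sizes a laptop handles in a couple of
minutes, chosen as the smallest cohorts at which the properties are
stable: parameter recovery uses a 10-item, 5-category bank at $n = 1000$
(RMSE bounds 0.15 on $a$, 0.20 on thresholds); the DIF power experiment
uses a 30-item bank at $n = 2000$ over 20 seeds, planting the shift in the
item whose discrimination is closest to the bank mean and scanning the
planted item against a fixed set of null items; the stop-rule gradient
uses the full 98-item default bank with a 150-person cohort across the
seven SE targets 0.2–0.8. On such cohorts the simulated gradient
reproduces the canonical pattern: stricter targets cost more items and buy
higher marginal reliability and higher agreement with the full-bank
estimate.

## Known limitations

* Unidimensional models only; no testlet, bifactor or multidimensional
  support, and no nominal response model.
* No item-exposure control or content balancing in the selector; maximum
  information will overuse high-discrimination items.
* Item parameters are treated as fixed during adaptive testing; estimation
  uncertainty from calibration is not propagated.
* No standard errors for item parameters, and no linking/concurrent
  calibration designs.
* The DIF scan is a single pass (no anchor purification) and covers a
  binary grouping only.
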