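---
title: "Decomposing the c-statistic at external validation: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decomposing the c-statistic at external validation: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(validisc)
```

## The model and the question

`validisc` works with binary-outcome logistic prediction models. A model
is developed on a development cohort D and externally validated on a
cohort V. Writing $\hat\beta_D$ for the development estimates and $X_D$,
$X_V$ for the two covariate matrices, the linear predictors are

$$
lp_D = X_D \hat\beta_D, \qquad lp_V = X_V \hat\beta_D ,
$$

both under the *development* coefficients. Discrimination is measured by
the concordance statistic $c$: the probability that, in a random
event/non-event pair, the event subject has the higher predicted risk
(the Mann–Whitney form of the area under the ROC curve; tied scores count
one half).

The question the package addresses: when $c$ at validation ($c^V$)
differs from the development value ($c^D$), is that because the
coefficients are invalid in the new population, or because the new
population's *case-mix* — the spread of its risk distribution — differs?
Both move $c^V$, and only the first says anything about the model being
wrong.

## The measures

**SD of the linear predictor.** A population with a more heterogeneous
case-mix has a wider linear-predictor distribution. `casemix_summary()`
reports $\mathrm{SD}(lp_D)$, $\mathrm{SD}(lp_V)$ and their ratio
(validation over development). The SD uses the $n-1$ sample denominator;
at the sample sizes where these analyses are meaningful ($n \ge 40$) the
choice is immaterial. The measure is invariant to intercept changes, and
assumes an approximately symmetric linear-predictor distribution — for
strongly skewed risk distributions a single SD is a blunt summary and the
distributions should also be inspected graphically.

**Model-based c-statistic (mbc).** The c-statistic expected in the
validation case-mix *if the model's predicted probabilities were exactly
correct*. `model_based_c()` estimates it by outcome resimulation: each
validation subject $i$ with predicted probability $\hat p_i$ is
replicated `n_reps` times, synthetic outcomes are drawn
$y^*_{ir} \sim \mathrm{Bernoulli}(\hat p_i)$, and one pooled c-statistic
of the replicated $\hat p_i$ against the $y^*$ is returned. Two design
choices deserve note:

* *Which coefficients.* The mbc is computed from the development-fitted
  model's predicted probabilities on the validation covariates. That is
  what makes it a benchmark for the development model under the
  hypothesis that its predictions are correct; computing it from
  coefficients re-estimated on the validation sample would collapse it
  into the refitted benchmark and destroy the decomposition.
* *Aggregation.* One pooled c-statistic over all $n \times$ `n_reps`
  pseudo-subjects rather than the mean of `n_reps` per-replicate
  c-statistics. Pooling is the lower-variance estimator of the expected
  c-statistic and makes the Monte-Carlo error negligible at the default
  `n_reps = 100` (the minimum the estimator accepts; larger values are
  configurable).

The contrast $mbc - c^V$ isolates coefficient invalidity: case-mix
differences move $mbc$ and $c^V$ together.

**Refitted c-statistic.** `refitted_c()` refits the same model
specification on the validation data and reports its apparent
c-statistic there: the discrimination the model class can achieve in that
case-mix, an upper bound for judging $c^V$. For a single-predictor model
whose refit slope keeps the sign of the original slope, the refit is a
monotone transform of the same predictor, so $c^{refitted} = c^V$
exactly — a useful internal consistency check that the tests assert.

**Permutation test.** `permutation_test()` tests the null hypothesis that
D and V are samples from one homogeneous population. All $n_D + n_V$
subjects are pooled; in each of $k$ rounds they are randomly reassigned
to a permuted development set of size $n_D$ and a permuted validation set
of size $n_V$ (size-preserving reassignment keeps the permuted statistic
comparable to the observed one), the specification is refitted on the
permuted development set, and its c-statistic on the permuted validation
set is recorded. The p-value is the proportion of permuted c-statistics
*strictly below* the observed $c^V$ — one-sided, unsmoothed (no
$+1/(k+1)$ correction), so attainable p-values include exactly 0 and 1,
and ties with the observed value do not count. Defaults: $k = 1000$,
rejection at $p < 0.05$.

Degenerate permuted development sets (all-0 or all-1 outcomes) are
redrawn rather than dropped — dropping would bias the p-value toward
whichever tail the fittable splits favor. Redraws are counted and a
warning is raised if more than 1% of rounds needed one; with realistic
sample sizes and event rates redraws essentially never occur.

## Fitting: stabilized maximum likelihood

All fits are logistic regressions by IRLS with a tiny ridge penalty
($10^{-6}$) on the slopes, never the intercept, and an iteration cap of
100. With samples of 40 and true slopes of 3, complete or quasi-complete
separation occurs in a nontrivial fraction of generated samples; plain ML
then diverges. The penalty keeps estimates finite while being far below
reporting precision for non-separated fits, and every downstream measure
in the package (c-statistics, linear-predictor SDs, mbc) is rank- or
spread-based, so the exact magnitude of a separated fit's coefficients is
immaterial. Discarding separated samples instead would bias the
simulation summaries. Convergence is declared on either the Newton step
(max absolute update $< 10^{-8}$) or the relative deviance change
($< 10^{-8}$, the criterion that terminates separated fits once the
linear-predictor ranking is stable); fits that exhaust the cap are
flagged `converged = FALSE`.

Fitted models always include an intercept. The simulation engine's
data-generating model has none (see below), which is a statement about
the generating mechanism, not about the analyst's model: an unrestricted
logistic regression is the standard prediction model, and the intercept
estimate is simply near zero under the generator's symmetric design.

## The simulation engine

`generate_scenario_pair()` draws
$x \sim N(0, \sigma_j^2)$, $y \sim \mathrm{Bernoulli}(\mathrm{logit}^{-1}(\beta_j x))$
independently for the development ($j = D$) and validation ($j = V$)
populations. The canonical grid (`scenario_grid()`) crosses three
parameter rows —

| scenario | $\sigma_D$ | $\sigma_V$ | $\beta_D$ | $\beta_V$ |
|---|---|---|---|---|
| homogeneous populations | 1 | 1 | 3 | 3 |
| different case-mix & predictor effects | 1 | 1.5 | 3 | 2 |
| different case-mix & same predictor effects | 1 | 0.75 | 3 | 3 |

— with 40, 100 or 200 subjects per set (events-per-variable roughly
20/50/100 at the implied ~50% event rate). These defaults *are* the study
conditions; they are constructor arguments only so that users can explore
other designs.

Per replicate, `run_replicate()` generates a fresh development/validation
pair (both sets are redrawn every replicate; redrawn whole if either has
all-0/all-1 outcomes, with a counter kept), fits on the development set,
and computes $c^D$ (apparent), $c^V$, the linear-predictor SDs and ratio,
mbc, the refitted c-statistic, and optionally the permutation test.
`run_study()` aggregates medians and interquartile ranges over
replicates, plus the rejection proportion.

**Seeding.** All randomness flows from explicit seeds: a study's master
seed spawns one sub-seed per replicate, so replicate $r$ is bitwise
reproducible in isolation; inside a replicate, generation, mbc draws and
permutation rounds consume one stream sequentially. No function draws
unseeded randomness when a seed is supplied.

**Problem sizes.** The package's own reproduction runs (the test suite
and `scripts/acceptance.R`) use 1000 replicates per scenario for the
median/IQR summaries — at that count the Monte-Carlo error of a median
c-statistic is below 0.002 — and 250 replicates with $k = 500$
permutation rounds (200 replicates at $n = 200$) for rejection
proportions, where the binomial standard error is about
$\sqrt{0.05 \cdot 0.95 / 250} \approx 0.014$ at the null rate and about
0.03 at a rate of 0.4: comfortably inside the comparisons the tests make.

## What the simulations show — and what they cannot

The engine reproduces the known behavior of the measures. Under
homogeneous populations all benchmarks agree with $c^V$ and the
permutation test rejects at its nominal 5% rate. When the validation
case-mix is wider but the true effects are weaker, the two distortions
offset in $c^V$ (it stays near the development value) while
$mbc - c^V \ge 0.03$ correctly flags the invalid coefficients — and the
permutation test rejects *less* often than under exact homogeneity: its
documented blind spot. When the case-mix narrows with identical effects,
$c^V$ drops, mbc and the refitted c track it (gap $\le 0.02$), the SD
ratio reads ~0.75 — and the permutation test increasingly "detects"
heterogeneity as $n$ grows (≈18% at $n = 40$ to ≈39% at $n = 200$)
although the model is perfectly valid.

The generator is deliberately minimal: one normal predictor, no
intercept, ~50% prevalence, independent samples. Passing the simulation
suite therefore demonstrates the estimators' behavior under controlled
case-mix and coefficient shifts; it does not exercise skewed or
multivariable case-mix, rare outcomes, miscalibrated intercepts, or
correlated predictors, all of which real validation studies bring. The
report format (`validate_external()`) accepts arbitrary numeric predictor
matrices, but interpretation of the SD ratio as "the" case-mix summary
leans on an approximately normal linear predictor.

Calibration — agreement between predicted probabilities and observed
outcomes — is a separate and equally necessary axis of validation that
this package does not assess.

## Numerical and degenerate-input conventions

* c-statistic: midrank (Mann–Whitney) computation, $O(n \log n)$,
  validated in the tests against an exhaustive $O(n^2)$ pairwise oracle;
  undefined (typed error) when either outcome class is absent.
* `sd_linear_predictor()` requires length ≥ 2; a constant development
  linear predictor makes the SD ratio NaN with a warning.
* `predict_probability()` clamps to the open interval (0, 1) at double
  precision, so resimulation never draws from a degenerate Bernoulli.
* p-value ties: permuted c-statistics exactly equal to the observed one
  never count as "smaller".
* Reports serialize to JSON with 17 significant digits, which round-trips
  doubles bitwise.
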