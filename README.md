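# validisc

Tools to interpret the change in discriminative performance — the
concordance (c-) statistic — of a clinical prediction model between its
development sample and an external validation sample, and a simulation
engine to study how the available summary measures behave.

## The problem

When a logistic prediction model is validated on data from a new setting,
its c-statistic (equivalently, the area under the ROC curve) almost never
matches the development value. The change confounds two distinct
phenomena:

* **case-mix**: a validation population with more (or less) heterogeneous
  patient characteristics spreads the predicted risks wider (or narrower),
  which by itself raises (or lowers) the c-statistic, with no change in
  the validity of the model; and
* **coefficient validity**: the regression coefficients may simply be
  wrong in the new population.

`validisc` implements the measures that disentangle the two, plus the
permutation test of development/validation homogeneity that tries to
summarize the change in a single p-value, so the two approaches can be
compared directly:

* the **SD of the linear predictor** `lp = X betahat` in each sample and
  the ratio `SD(lp_V) / SD(lp_D)` (both computed with the *development*
  coefficients) — a direct scalar case-mix measure;
* the **model-based c-statistic (mbc)**: the c-statistic expected in the
  validation case-mix *if the model's predicted probabilities were exactly
  correct*, estimated by replicating every validation subject at least 100
  times and drawing synthetic outcomes `y* ~ Bernoulli(phat_i)`;
  `mbc - c_V` therefore isolates coefficient invalidity;
* the **refitted c-statistic**: the apparent c-statistic of the same model
  specification re-estimated on the validation data — the upper bound
  achievable in that case-mix;
* the **permutation test**: pool all subjects, reassign them at random to
  sets of the original sizes, refit on the permuted development set,
  re-validate on the permuted validation set, repeat `k` times; the
  p-value is the proportion of permuted c-statistics strictly below the
  observed `c_V`.

The simulation engine generates development/validation pairs from
`x ~ N(0, sigma_j^2)`, `y ~ Bernoulli(logit^-1(beta_j x))` with separate
`(sigma, beta)` per population, and reproduces the three canonical
scenarios (homogeneous populations; more heterogeneous validation
case-mix with weaker effects; less heterogeneous case-mix with identical
effects) crossed with sample sizes 40/100/200 per set.

## Worked example

```r
library(validisc)

set.seed(42)
x_dev <- rnorm(500)                      # development cohort
dev <- dataset(rbinom(500, 1, plogis(3 * x_dev)), cbind(x = x_dev),
               sample_label = "development")
x_val <- rnorm(500, sd = 0.75)           # narrower validation case-mix,
val <- dataset(rbinom(500, 1, plogis(3 * x_val)), cbind(x = x_val),
               sample_label = "validation")   # same true coefficients

report <- validate_external(dev, val, k = 1000, n_reps = 100, seed = 1)
report
#> <validisc_report> (unlabeled)
#>   c (development, apparent)   0.93
#>   c (external validation)     0.90
#>   SD lp (dev) / (val) / ratio 3.34 / 2.67 / 0.80
#>   mbc (case-mix benchmark)    0.90
#>   c (refitted upper bound)    0.90
#>   permutation p (k = 1000)     0.04 [reject homogeneity]
```

Reading the numbers: the c-statistic dropped from 0.93 to 0.90 at
validation, but the mbc (0.90) and refitted c (0.90) sit exactly on the
observed value, and the linear-predictor SD ratio of 0.80 shows a
narrower validation case-mix — the drop is fully explained by case-mix,
not by invalid coefficients. The permutation test nevertheless rejects
homogeneity (p = 0.04): it reacts to a pure case-mix difference it cannot
distinguish from model invalidity, which is exactly the failure mode the
simulation engine quantifies.

A full scenario study:

```r
study <- run_study(scenario_grid()[[7]],  # narrower case-mix, n = 40
                   n_replicates = 1000, with_permutation = FALSE, seed = 7)
study
```

## Command-line interface

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "validisc", package = "validisc"))')
Rscript "$CLI" validate --dev dev.csv --val val.csv --outcome y \
    --predictors x1,x2 --permutations 1000 --seed 1 --out report.json
Rscript "$CLI" simulate --scenario all --replicates 1000 --seed 1 --out study
```

`validate` writes a JSON report with every quantity above plus the seeds
and settings needed to reproduce it; `simulate` writes a tidy CSV and a
JSON summary (median and interquartile range per metric, rejection
proportion per scenario).

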