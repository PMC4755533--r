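Package: validisc
Title: Discrimination Benchmarks and a Permutation Test for External
    Validation of Clinical Prediction Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies and decomposes changes in the concordance
    (c-) statistic of a logistic prediction model between a development
    sample and an external validation sample. Separates the effect of
    case-mix heterogeneity from the effect of invalid regression
    coefficients using the standard deviation of the linear predictor,
    the model-based c-statistic (mbc) obtained by outcome resimulation,
    and the refitted c-statistic. Implements the permutation test of
    development/validation homogeneity based on the change in
    c-statistic, and a simulation engine that evaluates the test against
    the benchmark measures across case-mix and coefficient-validity
    scenarios.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
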