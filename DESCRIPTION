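Package: adipomr
Title: Observational and Mendelian Randomization Analysis of a Circulating
    Biomarker and Disease Risk
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An end-to-end toolkit for testing whether a circulating
    biomarker (motivating case: plasma adiponectin) causally affects
    disease outcomes such as heart failure and atrial fibrillation.
    Implements observational Cox proportional hazards modelling with age
    as the timescale and delayed entry (restricted cubic splines,
    quartile contrasts, interaction likelihood-ratio tests,
    reverse-causation sensitivity analyses); construction and validation
    of allele-score genetic instruments (Hardy-Weinberg tests, F
    statistics, confounder screens); one-sample Mendelian randomization
    via the Wald-type estimator; two-sample summary-data Mendelian
    randomization (inverse-variance weighted, MR-Egger, weighted median,
    weighted mode) with allele harmonization and LD pruning; non-linear
    Mendelian randomization via doubly-ranked stratification with
    fractional-polynomial and piecewise-linear causal curves; and a
    synthetic-cohort generator that reproduces the statistical structure
    these analyses assume, so the whole pipeline is testable without
    access-restricted data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    survival
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
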