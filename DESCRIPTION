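Package: hybridDIF
Title: Hybrid Ordinal-Regression/IRT Differential Item Functioning Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detects differential item functioning (DIF) in ordinal
    (Likert-type) patient-reported outcome scales with the hybrid
    ordinal-logistic-regression/item-response-theory approach: graded
    response model calibration by marginal maximum likelihood, expected a
    posteriori trait scoring, nested cumulative-logit DIF models compared
    by Nagelkerke pseudo-R-squared change, Monte-Carlo simulation of
    empirical detection thresholds, iterative item purification,
    group-specific recalibration of flagged items, and cumulative
    individual-level DIF impact with a salience criterion. Includes
    exploratory dimensionality assessment (polychoric correlations,
    permutation-based parallel analysis, the Empirical Kaiser Criterion)
    and a multi-cohort synthetic-data generator modelled on the 32-item
    HIV Stigma Scale study design.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    MASS,
    mvtnorm,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
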