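Package: ogttclear
Title: Insulin Secretion, Clearance and Sensitivity from the Oral Glucose
    Tolerance Test
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Estimates insulin secretion rate by regularized C-peptide
    deconvolution under a two-compartment kinetic model with population
    parameters standardized for anthropometry, and derives the panel of
    oral-glucose-tolerance-test (OGTT) indices used in paediatric
    metabolic phenotyping: fasting and post-load insulin clearance,
    hepatic insulin resistance index (HIRI), Matsuda whole-body insulin
    sensitivity, Stumvoll metabolic clearance rate, HOMA-IR and beta-cell
    glucose sensitivity. Includes obstructive sleep apnea severity
    grading from the apnea-hypopnea index, a nonparametric cohort
    statistics layer (group contrasts, point-by-point curve comparison,
    Spearman correlations), and a synthetic-cohort generator with known
    ground truth for validation and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    jsonlite,
    nortest,
    rlang,
    stats,
    tibble,
    utils,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    optparse,
    pracma,
    readr,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
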