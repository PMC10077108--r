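Package: egfrtraj
Title: Predicting Individual eGFR Trajectories in Type 2 Diabetes and CKD
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Longitudinal prediction of estimated glomerular filtration rate
    (eGFR) for people with type 2 diabetes and chronic kidney disease. Fits a
    linear mixed-effects model with per-individual random intercepts and
    time slopes nested within country, in which the baseline eGFR is part of
    the outcome vector; updates a new individual's random effects by
    empirical-Bayes conditioning on a single baseline eGFR; derives
    individual eGFR slope distributions and probabilities of rapid
    progression (decline steeper than -3 mL/min/1.73 m2 per year); and
    validates predictions by leave-one-country-out cross-validation with
    per-follow-up-year predicted R2, concordance and calibration slope plus
    cluster-bootstrap confidence intervals. Includes a multi-country
    synthetic cohort generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    readr,
    jsonlite,
    yaml,
    Matrix,
    Rcpp,
    stats,
    utils,
    tools,
    withr
LinkingTo: Rcpp
Suggests:
    lme4,
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
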