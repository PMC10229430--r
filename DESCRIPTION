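Package: dosedi
Title: Simulation and Analysis of Beta-Cell Function Dose-Response Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for designing, simulating and analysing four-arm randomized
    trials of diet and exercise dose on beta-cell function in type 2 diabetes.
    Provides a synthetic-cohort generator with known ground truth (stratified
    permuted-block randomization, hyperglycemic-clamp and mixed-meal time
    series), two-compartment C-peptide kinetics with regularized deconvolution
    of insulin secretion rate, clamp disposition/sensitivity indices, Steele
    non-steady-state stable-isotope glucose turnover, meal-test indices
    (Matsuda, insulinogenic, oral disposition index), a constrained-baseline
    longitudinal model with geometric-mean-ratio reporting, dose-trend and
    hierarchical gatekeeping inference, continuity-corrected odds ratios,
    multiple-imputation sensitivity analysis, contrast power, and causal
    mediation with bias-corrected and accelerated bootstrap intervals.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    boot,
    nlme,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
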