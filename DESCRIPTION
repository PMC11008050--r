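Package: dmfic
Title: Atrophy-Modulated Feedback Inhibition in Whole-Brain Dynamic Mean
    Field Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Simulates whole-brain resting-state activity with a dynamic mean
    field (DMF) model in which regional grey-matter atrophy modulates the
    local feedback inhibition control (FIC) weight through a single coupling
    parameter sigma. Provides baseline FIC calibration to a physiological
    firing-rate band, Balloon-Windkessel BOLD generation, structural
    similarity (SSIM) comparison of functional connectivity matrices,
    Gaussian-process Bayesian optimization of sigma against empirical FC
    targets, atrophy-specificity experiments, cohort-level statistics
    (w-scores, regressions, ANCOVA, Levene, FDR-corrected t-tests, Cohen's d),
    and model-based extrapolation of connectivity change with disease
    duration, including resting-state-network overlap scoring. A synthetic
    data module generates connectomes, atrophy maps, cohorts, and FC targets
    with known ground truth for parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    dplyr,
    ggplot2,
    rlang,
    yaml,
    car,
    signal,
    generics
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
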