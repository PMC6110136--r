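Package: ddgbench
Title: Benchmarking Predictors of Mutation-Induced Binding Free-Energy Changes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Statistical toolkit for benchmarking physics-based predictors of the
    change in inhibitor binding free energy (ddG) caused by protein point
    mutations, against cell-viability or binding-affinity data. Converts IC50 or
    pIC50 potencies to binding free-energy changes, classifies mutations as
    resistant or susceptible at fold-change thresholds, builds truth tables and
    classification/quantitative error metrics with censoring bookkeeping,
    estimates uncertainties by percentile bootstrap, sweeps ROC curves with
    trapezoidal AUC, fits slope-scaled and inverse-variance consensus predictors,
    and deconvolves experimental and statistical noise from a predictor's
    intrinsic error with a hierarchical Bayesian measurement-error model.
    Includes a synthetic benchmark generator with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    coda,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rjags,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
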