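Package: respacclim
Title: Thermal Acclimation Analysis of Plant Tissue Dark Respiration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing short-term thermal acclimation of dark
    respiration across plant tissues (leaves, stems, roots). Fits the
    exponential-quadratic temperature-response model to per-individual flux
    series, regresses the fitted parameters on acclimation temperature with
    mixed-model analysis of covariance (Wald chi-square tests, least-squares
    mean trends, planned photosynthetic versus non-photosynthetic contrasts),
    reconstructs acclimated respiration surfaces, and computes the
    homeostasis ratio statistic and the ratio of acclimated respiration to
    photosynthetic capacity. Includes a synthetic-data generator that
    emulates the unbalanced multi-species, multi-tissue study design so
    every stage of the pipeline can be exercised and validated without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    car,
    dplyr,
    emmeans,
    generics,
    ggplot2,
    jsonlite,
    lme4,
    lmerTest,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    pbkrtest,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
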