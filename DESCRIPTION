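Package: enclaveVOC
Title: Joint Ethnic-Enclave and Ambient VOC Exposure Analysis for
    Gestational Diabetes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for joint social-environmental exposure analysis of
    gestational diabetes mellitus (GDM) risk among Asian/Pacific Islander
    (API) pregnancies. Computes area-level residential segregation measures
    (API population density, API-White dissimilarity, API isolation) from
    small-area counts aggregated to regions, classifies regions as ethnic
    enclaves via population-based tertiles, averages ambient volatile
    organic compound (VOC) concentrations over preconception and
    first-trimester exposure windows and dichotomizes them at the 75th
    percentile, builds four-level joint VOC-by-enclave exposure categories,
    and fits per-VOC random-intercept logistic regressions with multiple
    imputation of body mass index, mother-clustered sandwich standard
    errors, and Benjamini-Hochberg false discovery rate control. A
    synthetic nested-cohort generator with known ground truth makes the
    whole pipeline testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    glmmTMB,
    jsonlite,
    lme4,
    nnet,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    sandwich,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
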