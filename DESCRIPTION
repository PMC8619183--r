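Package: posturadapt
Title: Postural Adaptation Analysis for Repeated Surface Perturbations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Feature extraction and multivariate modelling for studies of
    postural adaptation to repeated support-surface perturbations in older
    adults. Extracts feedforward and feedback kinematic features from joint
    angle time series, EMG co-contraction indices from bilateral tibialis
    anterior and gastrocnemius recordings, and 95% prediction-ellipse sway
    areas from centre-of-pressure traces. Fits hierarchical NIPALS PCA base
    models and an OPLS-DA discriminant top model with cross-validated Q2,
    jackknife coefficient confidence intervals and permutation validation.
    Includes a seeded synthetic-cohort generator that emulates the data
    structure of a faller / non-faller perturbation study so the full
    pipeline is testable without human data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
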