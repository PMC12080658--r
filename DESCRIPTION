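Package: rpepipe
Title: Reward Prediction Error Modelling and Model-Based fMRI Pipeline
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for probabilistic monetary
    reward learning studies. Generates the 10-pair / 160-trial task with
    80/20 rewarded and 50/50 bivalent contingencies, simulates Q-learning
    agents with a softmax choice rule, fits learning-rate and temperature
    parameters by maximum likelihood, applies behavioral and head-motion
    quality-control filters, builds first-level fMRI design matrices with a
    trial-wise reward-prediction-error parametric modulator convolved with a
    gamma response function, estimates voxelwise GLMs, and performs
    group-level inference (group means, group differences, covariate-adjusted
    symptom-correlation maps) with permutation-based cluster family-wise
    error correction. A synthetic-cohort generator with planted effects makes
    every stage testable end to end without any external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    lhs,
    purrr,
    readr,
    rlang,
    RNifti,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
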