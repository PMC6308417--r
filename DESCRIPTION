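Package: insolegait
Title: Gait Analysis from Pressure-Insole Ground Reaction Forces
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for free-walking gait recorded with in-shoe
    pressure insoles. From two per-foot vertical ground-reaction-force (GRF)
    time series it detects gait events (foot-strike, toe-off), removes turn
    strides, and computes 28 kinematic parameters (timing, stride-to-stride
    variability, gait asymmetry, bilateral phase and the phase coordination
    index) and 24 kinetic parameters describing the M-shaped stance force
    profile. Includes group comparisons (Kruskal-Wallis with Wilcoxon
    post-hocs), ReliefF/RReliefF feature ranking, leave-one-out linear
    discriminant classification, and a synthetic-cohort generator with full
    ground truth for validating every stage.
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    MASS,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
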