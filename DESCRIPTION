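Package: wearals
Title: Multi-Sensor Remote Monitoring Analysis for ALS Clinical Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested, reusable pipeline for analysing multi-sensor remote
    monitoring data from ALS clinical studies: accelerometer-derived activity
    scoring and 3-class activity classification with leave-one-patient-out
    validation, nonwear detection and wear-time accounting, windowed heart-rate
    variability (RMSSD, LF/HF via Lomb-Scargle) with missing-data sufficiency
    rules, in-clinic speech feature extraction (F0, formants, phonation time,
    speaking rate), and longitudinal cohort endpoint aggregation. Includes a
    fully synthetic cohort generator (sensor streams, reference-task sessions,
    speech audio, adherence and dropout) with known ground truth for end-to-end
    validation.
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
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    xgboost
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
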