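Package: ppgbp
Title: Cuffless Blood Pressure Estimation from Wrist Photoplethysmography
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating systolic blood pressure from a single
    wrist photoplethysmogram (PPG) channel without a cuff. The package
    conditions the raw PPG, computes the acceleration plethysmogram (APG,
    the second time derivative), detects the a-e fiducial waves of each
    beat, assembles a twenty-feature vector (wave heights, latencies,
    height ratios, the APG index, pulse rate and questionnaire
    covariates), and fits a stepwise-selected multiple regression for
    systolic pressure alongside a conventional pulse-transit-time
    baseline. It also classifies 24-hour blood-pressure profiles into
    nocturnal dipping patterns, summarises daily and weekly variability,
    and ships a synthetic-waveform generator with exact fiducial ground
    truth so every stage can be validated against known answers.
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
    withr,
    xml2,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
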