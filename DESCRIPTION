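Package: tissuepk
Title: Target-Site Pharmacokinetics from Microdialysis: Recovery
    Calibration, Non-Compartmental Analysis and fAUC/MIC Target
    Attainment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing antibiotic exposure in plasma and the
    interstitial fluid (ISF) of subcutaneous tissue sampled by
    microdialysis. Converts raw dialysate concentrations into ISF
    profiles via retrodialysis recovery calibration, performs
    non-compartmental pharmacokinetic analysis (linear-up/log-down
    trapezoidal AUC, terminal log-linear regression, MRT, clearance and
    steady-state volume), evaluates fAUC24/MIC target attainment over an
    MIC grid, and provides the cohort-level statistical layer
    (exposure-weight regression, Fisher-Z correlation intervals,
    longitudinal linear mixed models on log concentrations, and
    correlation-based sample-size computation). A synthetic obese versus
    non-obese cohort generator reproducing a 600 mg / 30 min linezolid
    infusion study design makes the whole pipeline testable without
    patient-level data.
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
    jsonlite,
    lme4,
    purrr,
    readr,
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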