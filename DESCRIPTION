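Package: adipoquant
Title: Adolescent Body-Fat Estimation Batteries and Cardiometabolic Risk Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements a twelve-method battery of adolescent body-fat estimates
    (ten anthropometric prediction equations spanning skinfold densitometry with
    Siri conversion, skinfold regressions, BMI-based forms, and bioimpedance
    fat-free-mass equations), derived cardiometabolic biomarkers (Friedewald LDL,
    lipid ratios, HOMA-IR) with clinical risk flags, and a multi-stage regression
    screen (bivariate P < 0.20 admission, sex-adjusted multiple regression with
    Shapiro-Wilk residual gating, White heteroskedasticity test with small-sample
    robust variances, and variance-inflation diagnostics) that ranks body-fat
    methods by the number of cardiovascular risk factors each predicts. A
    calibrated synthetic-cohort generator emulates the two-group eutrophic /
    overweight study design so every pipeline stage is testable without subject
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    rlang,
    readr,
    sandwich,
    lmtest,
    nortest,
    yaml
Suggests:
    testthat (>= 3.0.0),
    tidyr,
    withr,
    jsonlite,
    knitr,
    ggplot2
Config/testthat/edition: 3
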