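Package: score2plus
Title: Augmenting SCORE2 Cardiovascular Risk Prediction with Biomarker and
    Polygenic Scores
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for evaluating the incremental value of clinical
    biomarkers, NMR metabolomic scores, and polygenic scores added to the
    SCORE2 10-year cardiovascular disease risk model. Implements the SCORE2
    linear predictor and calibrated absolute risk with ESC 2021 risk
    categories, sex-stratified Cox proportional-hazards augmentation models
    with SCORE2 as a fixed offset, elastic-net training of NMR metabolomic
    risk scores, sex-stratified Harrell's C-index and paired delta-C
    inference, categorical net reclassification improvement, and
    standardization of risk stratification to external demographics and
    incidence rates to model population screening outcomes (events
    prevented, numbers needed to screen and treat) under population-wide
    and targeted re-screening strategies, with bootstrap uncertainty. A
    synthetic cohort generator with known proportional-hazards structure
    supports end-to-end testing without access to restricted cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    glmnet,
    jsonlite,
    stats,
    survival,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
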