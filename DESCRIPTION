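Package: depscreen
Title: Multimodal Depression-Screening Signals from Social-Media Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying likely-depressed social-media users from
    heterogeneous signals: a calibrated synthetic cohort generator (profiles,
    tweets, images, face-emotion annotations, reply networks), computational
    aesthetic image features (colorfulness, naturalness, HSV moments),
    facial-emotion pooling, lexicon-based text features and demographic
    inference (age rules, weighted-lexicon scores, adult-development age
    groups), egocentric network metrics, shadow-feature (Boruta-style)
    selection, a second-order gradient-boosted tree classifier with additive
    log-odds explanations, and the statistical evaluation layer (chi-square
    association, Bonferroni-corrected group tests, Cohen's kappa, stratified
    cross-validation).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    jsonlite,
    png,
    igraph,
    ranger
Suggests:
    testthat (>= 3.0.0),
    withr,
    xgboost,
    knitr,
    rmarkdown
Config/testthat/edition: 3
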