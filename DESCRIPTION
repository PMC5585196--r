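Package: inphconn
Title: Resting-State Connectome Classification of Normal Pressure Hydrocephalus
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for resting-state functional-connectivity
    analysis of idiopathic normal pressure hydrocephalus (iNPH): seeded
    synthetic ROI BOLD cohorts with severity-dependent interhemispheric
    correlation structure, confound regression and band-pass denoising with
    correlation-distribution quality control, ROI-pair Pearson/Fisher-z
    connectivity features, t-test feature filtering with class-weighted
    linear support-vector machines under leave-one-out cross-validation
    (binary diagnosis and one-against-all severity grading), exact binomial
    significance, and interpretation of linear-SVM weights by hemisphere
    partition with Wilcoxon rank-sum comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    e1071,
    RNifti,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Roxygen: list(markdown = TRUE)
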