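Package: entroscan
Title: Optimized Multiscale Entropy Biomarkers for Regional Brain Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Multiscale sample entropy analysis of regional physiological time
    series (e.g. resting-state fMRI BOLD signals parcellated by the AAL atlas),
    with objective selection of the entropy parameters (embedding dimension m,
    similarity factor r, scale factor tau) from two-group comparisons via
    significant-region counts and ROC/AUC, selection of biomarker regions by
    two-sample testing, and classification of subjects with a Parzen-window
    probabilistic neural network under stratified N-fold cross-validation.
    Includes a synthetic-cohort generator with planted, scale-localized
    complexity differences so the whole pipeline is testable without any
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    tidyr,
    tibble,
    readr,
    rlang,
    jsonlite,
    ggplot2,
    generics,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
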