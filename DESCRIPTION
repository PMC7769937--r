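Package: facemotion
Title: Facial-Movement Prediction Models for Multi-Dimensional
    Psychological Symptoms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds and evaluates prediction models that map time-series
    characteristics of 3D facial key-point motion onto six SCL-90 symptom
    dimensions (interpersonal sensitivity, depression, anxiety, hostility,
    phobic anxiety, psychoticism). Provides a synthetic cohort generator
    with latent-trait ground truth, landmark preprocessing (reference-point
    translation, three-frame smoothing, frame windowing, parity split-half,
    differencing), a catalogue of 30 time-series characteristics yielding a
    3,240-column feature matrix, F-value feature selection with LASSO
    regression and five-fold out-of-fold prediction, and psychometric
    evaluation of the resulting models: split-half reliability, criterion
    validity, and a multitrait-multimethod matrix with convergent and
    discriminant verdicts.
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
    MASS,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp
Suggests:
    e1071,
    glmnet,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
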