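Package: pomometrics
Title: Morphometric Feature Extraction and Ensemble Classification for
    Fruit Cultivars
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for identifying clonally propagated fruit cultivars from
    non-destructive morphometric measurements.  Implements landmark-based
    geometric morphometrics (TPS file input, generalized Procrustes
    superimposition, view averaging, centroid size, Procrustes ANOVA for
    digitisation error, shape principal components), linear morphometrics
    (calliper measurements, weight, outline areas, an RGB colour principal
    component), a repeated stratified cross-validation harness over a
    configurable classifier suite, and a per-class-accuracy-weighted
    "manual ensemble" that arbitrates between a linear-trait classifier
    and a shape classifier.  A synthetic-study generator with controllable
    within-cultivar noise, digitisation noise, and complementary
    shape-vs-size separability supports testing the whole pipeline without
    photographs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    class,
    dplyr,
    e1071,
    generics,
    ggplot2,
    glmnet,
    MASS,
    nnet,
    purrr,
    randomForest,
    rlang,
    rpart,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    caret,
    jsonlite,
    readxl,
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
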