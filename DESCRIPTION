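Package: attnmil
Title: Attention-Based Multiple Instance Learning for Weakly Supervised
    Whole-Slide Image Risk Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Two-stage weakly supervised classification of whole-slide
    histopathology images from slide-level labels only. A patch-level CNN
    scorer trained under weak supervision assigns every tumor-region patch a
    discrimination score (distance of its class probability from the 0.5
    decision boundary); the top-K scored patches per slide are embedded into a
    bag of feature vectors ("intelligent sampling"); a gated attention-based
    multiple instance learning model pools the bag into a meta-instance and
    classifies the slide. Includes a synthetic cohort generator emulating
    proliferating-cell density contrast, annotation-driven tiling from GeoJSON
    tumor-region polygons, cross-validation protocols (k-fold with hold-out
    testing and leave-two-out), bootstrap confidence intervals, bag-size
    ablation harnesses, and attention heatmap rendering.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    mgcv,
    png,
    Rcpp,
    stats,
    tiff,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
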