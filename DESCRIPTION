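Package: BoneAgeNet
Title: Bone Age Assessment from Hand Radiographs with Unsupervised
    Hand Localization and a Gender-Embedded Regression Network
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Computer-aided bone age assessment from pediatric hand-wrist
    radiographs. Provides a per-image unsupervised hand localizer based on
    differentiable feature clustering (a small convolutional network trained
    on the single target image with a feature-similarity plus
    spatial-continuity loss), an image pre-processing pipeline (background
    removal, connectivity analysis, maximum-area crop, histogram
    equalization), a MobileNetV3-style regression network with a 24-dimension
    gender embedding fused into the image feature vector, and training and
    evaluation utilities for standardized bone-age regression. A seeded
    synthetic-radiograph generator makes the whole pipeline testable without
    clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    EBImage,
    jsonlite,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
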