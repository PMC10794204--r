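Package: vhsnet
Title: Vertebral Heart Scale Estimation from Thoracic Radiographs with a
    Regressive Vision Transformer
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for automatic vertebral heart scale (VHS) scoring of
    canine thoracic radiographs. Implements a pyramid vision transformer
    with spatial-reduction attention that regresses the six anatomical
    keypoints defining the heart's long and short axes and the vertebral
    reference segment, a differentiable orthogonal layer enforcing
    perpendicularity of the two cardiac axes, VHS computation and
    three-class cardiomegaly grading, a seeded synthetic radiograph
    generator with exact ground-truth landmarks, a few-shot coarse-label
    bootstrap, and evaluation utilities (confusion matrices, one-vs-rest
    AUC, intraclass correlation).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
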