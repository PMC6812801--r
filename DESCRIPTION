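Package: parafovea
Title: Parafovea-Anchored Evaluation of Saliency-Map Predictions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Evaluates whether a single saliency-predicted point of interest
    could support rapid visual categorization under fixed central fixation.
    Converts visual angle to pixels for a given display geometry, builds
    parafovea disc masks, scores predicted points against hand-drawn target
    masks with four increasingly strict region-of-interest hit measures,
    calibrates overlap thresholds against human accuracy, quantifies center
    bias of targets and predictions, implements an ideal decision stage with
    confusion-matrix accuracy, analyses categorization accuracy as a function
    of target-parafovea overlap (including a parafoveal image-cropping
    transform), and generates synthetic stimulus sets with controllable
    center bias and predictor accuracy so every stage is testable without
    the original private stimulus collections.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    png,
    EBImage,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: Visualization, Classification
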