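Package: peelnet
Type: Package
Title: Multi-Stream Image Classification and Cross-Device Adaptation for
    Dried Citrus Peel Authentication
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Image-based vintage and origin authentication of Citri
    Reticulatae Pericarpium (dried citrus peel). Implements
    grayscale-deviation bounding-box refinement for exocarp/albedo
    localization, a three-branch convolutional classifier with
    channel-level feature interaction and fusion, and model-agnostic
    meta-learning (MAML) for few-shot adaptation across capture devices,
    together with a synthetic peel-image generator with ground-truth
    geometry so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    EBImage,
    Rcpp,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    MASS,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: Classification, FeatureExtraction
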