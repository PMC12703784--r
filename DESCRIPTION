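Package: weedseg
Title: Domain-Generalized Crop and Weed Segmentation via Stochastic
    Feature-Space Style Transfer
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Training and evaluation toolkit for pixel-level crop/weed
    segmentation models that must generalize from controlled "laboratory"
    imagery to unconstrained field scenes. Implements stochastic style
    transfer in feature space through a variational autoencoder over
    channel statistics (random adaptive instance normalization), an
    adversarial feature-normalization module trained through a gradient
    reversal layer, the combined two-phase training protocol, pixel-level
    segmentation metrics (mIoU, micro precision/recall/F1, merged weed
    IoU), and a seeded synthetic paddy-scene simulator with a controllable
    laboratory-to-field domain shift for benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    png,
    jsonlite,
    yaml,
    stats,
    grDevices,
    graphics,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
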