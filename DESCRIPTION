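Package: hsiband
Title: Reconstruction-Assisted Band Selection for Hyperspectral Fruit Quality
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A select-reconstruct-predict pipeline for non-destructive
    soluble-solids-content (SSC) regression from visible/near-infrared
    hyperspectral cubes. Implements spectral-spatial attention, a
    probability-based differentiable band selector with a soft pass-count
    budget, a lightweight encoder-decoder reconstruction branch, a compact
    convolutional regression head, a three-stage progressive training
    schedule with frequency-based top-K band fixation, reflectance
    calibration and patch preprocessing, a distribution-balanced dataset
    splitter, reconstruction and regression metrics, and a synthetic
    fruit-phantom generator with planted informative bands for end-to-end
    validation without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    tiff,
    yaml,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
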