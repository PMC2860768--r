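Package: qlfquant
Title: Quantitative Light-Induced Fluorescence Lesion Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies early enamel demineralization from quantitative
    light-induced fluorescence (QLF) images. Reconstructs the sound-enamel
    fluorescence level inside a user-drawn polygon region of interest by a
    two-step two-dimensional linear interpolation anchored on 3x3-smoothed
    border intensities, computes per-pixel and maximum percent fluorescence
    loss with a cold-spot-rejecting robust estimator, renders loss maps
    through the Fire look-up table, and calibrates percent fluorescence loss
    against histological demineralization depth by linear regression with
    inverse prediction. Includes a synthetic tooth-phantom generator with
    known ground truth for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    png,
    tiff,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
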