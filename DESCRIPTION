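Package: aminospec
Title: Estimation of Amino Acid Contents in Maize Leaves from Hyperspectral Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Workflow for estimating the contents of 24 free amino acids in
    fresh maize leaves from visible/near-infrared hyperspectral images
    (400-1000 nm, 300 channels). Implements NDVI-threshold leaf segmentation
    of ENVI-format cubes, Savitzky-Golay spectral smoothing, NIPALS partial
    least squares regression with leave-one-out PRESS component selection,
    two-stage sensitive-band screening (coefficient-of-variation range
    partition followed by coefficient-sorted backward elimination with
    frequency voting over resampled repetitions), and a repeated 70/30
    holdout evaluation harness reporting R2, RMSE, relative error and RPD.
    Includes a calibrated synthetic-study generator with planted spectral
    signatures so the full pipeline is testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    signal,
    stats,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
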