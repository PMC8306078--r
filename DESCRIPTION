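Package: hyperpls
Title: Hyperspectral PLS Calibration of Internal Fruit Constituents
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Chemometric calibration pipeline for predicting internal
    constituents (vitamin C, phenols, soluble solids, acidity) of intact
    fruit from hyperspectral reflectance images. Implements spectral
    pretreatment chains (Savitzky-Golay smoothing and derivatives, decadic
    absorbance transform, mean centering) with train/apply semantics, PLS1
    regression with leave-one-out cross-validation and PRESS-ratio latent
    variable selection, backward interval-PLS wavelength elimination,
    cross-validation F-statistic outlier removal, stratified calibration
    workflows, pixel-wise constituent mapping, ENVI and TIFF hyperspectral
    cube input/output, and a Beer-Lambert synthetic data generator for
    validation without proprietary data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    yaml,
    png,
    signal,
    EBImage,
    tiff,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
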