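Package: aromahsi
Title: Hyperspectral Prediction of Apple Aroma Chemical Groups
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An analysis pipeline for non-destructive prediction of apple
    volatile aroma content from visible/near-infrared hyperspectral images.
    Provides ENVI cube input/output with dark/white reflectance calibration,
    moderate-reflection region-of-interest extraction, spectral pre-treatments
    (standard normal variate, Savitzky-Golay first derivative, column-wise
    standardization), internal-standard relative quantification of GC-MS
    compound tables with chemical-class grouping, Monte-Carlo cross-validation
    outlier screening, grid-search selection of characteristic wavelengths with
    random-forest regression, calibration/validation metrics (R2, RMSE, RPD),
    and pixel-wise/object-wise chemical concentration maps. A synthetic-data
    module generates apple-like cubes and compound tables with known ground
    truth so the full pipeline is testable without instrument data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    jsonlite,
    ranger,
    EBImage,
    png
Suggests:
    testthat (>= 3.0.0),
    signal
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
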