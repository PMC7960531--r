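Package: ramanmargin
Title: Image-Guided Raman Spectroscopic Probe Tracking and Tumor Margin
    Delineation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation-backed implementation of an image-guided Raman
    spectroscopic probe-tracking system for surgical margin delineation.
    Tracks a handheld fiber-optic probe in video via HSV segmentation of
    colored fiducial markers with ratiometric tip extrapolation, classifies
    Raman spectra with a preprocessing chain (fingerprint-region crop,
    asymmetric Whittaker background subtraction, normalization,
    Savitzky-Golay filtering) followed by PLS-DA with Venetian-blinds
    cross-validation, accumulates spatial diagnoses into mm-calibrated
    lesion boundaries with adjustable safety margins, and quantifies
    tracking and delineation accuracy against ground truth. Includes
    synthetic generators for spectra, probe videos, and fluorescence
    phantom images so every workflow runs with known ground truth.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    Matrix,
    grDevices,
    jsonlite,
    png,
    signal,
    stats,
    utils,
    withr,
    yaml
Suggests:
    mixOmics,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
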