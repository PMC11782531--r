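Package: ccdnoise
Title: Noise Modelling and Calibration for Scintillation-Coupled CCD Detectors
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A complete mixed Poisson-Gaussian noise model for
    scintillation-based CCD cameras as used in transmission electron
    microscopy. Provides a forward simulator of the image-formation chain
    (correlated beam electrons, detector point-spread-function blur,
    per-pixel gain variation, dark current, per-quadrant read-out/row/offset
    noise, polynomial gain non-linearity, brighter-fatter blur) and the full
    calibration suite built on it: detector-noise decomposition, gain
    reference construction with uncertainty, autocovariance and
    Pearson-coefficient machinery via the Wiener-Khinchin theorem, detector
    PSF reconstruction with beam-correlation subtraction, photon-transfer
    non-linearity correction, brighter-fatter analysis, and propagation of
    all noise terms under pixel binning including an EELS spectrum noise
    model.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    tiff,
    jsonlite,
    minpack.lm
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
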