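Package: aokit
Title: Adaptive Optics Set-Up and Correction on a Simulated Bench
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for setting up and operating adaptive optics (AO) in
    microscopy without physical hardware: a Zernike wavefront core (Noll
    indexing, synthesis, least-squares decomposition, RMS error), a simulated
    bench (deformable mirror with coupled influence functions, direct,
    interferometric and Shack-Hartmann wavefront sensors, Fourier-optics image
    formation), automated influence-matrix calibration with thresholded SVD
    pseudo-inversion, characterisation assays of Zernike-mode recreation
    accuracy, closed-loop wavefront flattening, sensorless correction with
    pluggable image-quality metrics and Gaussian peak fitting, and IsoSense
    structured-illumination pattern generation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    stats,
    tiff,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
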