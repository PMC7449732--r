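Package: hddot
Title: Wearable High-Density Diffuse Optical Tomography Simulation and Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models a modular, wearable high-density diffuse optical
    tomography (HD-DOT) instrument and implements the full image-analysis
    pipeline for it: dual-integration charge acquisition with saturation
    handling, channel quality control, kurtosis-wavelet motion correction,
    band-pass filtering, the modified Beer-Lambert law, short-separation
    regressed haemodynamic response deconvolution, a semi-infinite-medium
    diffusion forward model, multispectral first-order Tikhonov image
    reconstruction via LSQR, and sign-flip permutation group statistics
    with max-T family-wise error control. A synthetic-data generator
    emulates the instrument (intensities, physiology, motion artifacts,
    per-module accelerometry) so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    signal,
    jsonlite,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
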