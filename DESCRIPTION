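Package: fluorotherm
Title: Fluorescence Thermometry Reconstruction with Patch-Recurrent Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Synthetic benchmark generation and temperature-map reconstruction
    for quantum-dot fluorescence thermometry. Generates ground-truth
    temperature fields as solutions of the steady-state heat-diffusion
    equation, renders them into multi-channel 16-bit fluorescent images
    through a parametric quantum-dot emission model and spectral filter
    banks, and inverts the images back to per-pixel temperature with a
    family of patch-recurrent networks (one-directional, bidirectional and
    multi-directional sequence models over 1x5 pixel runs and 5x5 tiles)
    plus classical pointwise baselines (multivariate polynomial fit,
    random forest). Includes a microfluidic-chip scene simulator with a
    serpentine probe channel and single-known-point calibration, and an
    evaluation harness for reconstruction error, extrapolation behaviour
    and gradient-conditioned error analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Matrix,
    tibble,
    dplyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    jsonlite,
    tiff,
    ranger
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml,
    withr
Config/testthat/edition: 3
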