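Package: visdiscomfort
Title: Efficient-Coding Analysis of Visual Discomfort
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: A tested pipeline for studying visual discomfort through the lens
    of efficient coding. Synthesizes calibrated stimulus batteries (sinusoidal
    gratings, raised-radial-cosine band-pass noise, 1/f random-phase noise,
    high-contrast stripe textures), computes a feed-forward log-Gabor model of
    the primary visual cortex (total population response and response
    kurtosis), estimates low-level image statistics (Fourier spectral slope,
    box-counting fractal dimension, RMS and contrast-sensitivity-weighted
    contrast, first- and second-order edge-orientation entropy), analyzes
    steady-state visually evoked potential (SSVEP) recordings with a Welch
    spectral chain, and runs the dimension-reduction and mixed-model inference
    stages with synthetic-data parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    lme4,
    lmerTest,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
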