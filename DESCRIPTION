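Package: cosid
Title: Species Identification from Correlation-Spectroscopy Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for authenticating species from Fourier-transform
    mid-infrared (FT-MIR) absorbance spectra via spectral images. Simulates
    class-structured absorbance spectra, transforms each spectrum into
    synchronous, asynchronous and integrative two-dimensional correlation
    (2DCOS) maps through the Hilbert-Noda formalism, renders seven image
    kinds (1D curve, three 2D heatmaps, three 3D surface projections) as
    64x64 rasters, partitions samples with the Kennard-Stone algorithm, and
    trains and compares a radial-basis SVM, an Alexnet-style convolutional
    network and a 12-layer residual network, emitting a cross-model
    comparison table with confusion matrices and per-class sensitivity.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    e1071,
    ggplot2,
    generics,
    grDevices,
    jsonlite,
    png,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
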