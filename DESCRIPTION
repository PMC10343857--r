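Package: ir2dcos
Title: Two-Dimensional Correlation Spectroscopy Images and Residual-Network
    Classification of Infrared Spectra
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Toolkit for authenticating closely related plant species from
    mid-infrared absorbance spectra. One-dimensional spectra are expanded into
    generalized two-dimensional correlation spectroscopy (2D-COS) maps --
    synchronous, asynchronous (via the discrete Hilbert-Noda transform) and
    integrative -- under a sinusoidal intensity perturbation, rendered as
    fixed-size raster images, partitioned into training/test/external sets
    with a stratified holdout followed by the Kennard-Stone algorithm, and
    classified with a small residual convolutional network (identity and
    convolution residual blocks, batch normalization, global average pooling)
    trained by stochastic gradient descent with cross-entropy loss. A
    synthetic multi-class spectrum generator with characteristic fingerprint
    bands, class-specific peak intensities, baseline drift and noise makes
    the whole pipeline testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    grDevices,
    graphics,
    S4Vectors,
    SummarizedExperiment,
    png,
    jsonlite,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
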