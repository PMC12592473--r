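Package: chromoshape
Title: Loop-Capture Chromatin Polymer Simulation and Chromosome Shape Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Brownian dynamics of a self-avoiding bead-spring chromatin chain,
    with optional condensin loop-capture interactions (stochastic pairwise
    bonds between designated binding sites that form on proximity and turn
    over), together with an analysis pipeline for mitotic chromosome shape:
    covariance-eigenvalue length/width/depth and roundness, power-law
    length-to-width fits, exponential relaxation fits, Flory scaling-exponent
    estimation, and image-based chromosome arm measurement (moving-Gaussian
    FWHM widths and equal-area ellipse dimensions) validated on synthetic
    DAPI-like images.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    minpack.lm,
    tiff,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
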