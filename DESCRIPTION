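Package: moiremap
Title: Statistical Wiring Models of Visual Cortical Orientation Maps and
    Pinwheel Layout Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates the random feedforward (statistical) wiring model of
    orientation preference maps in primary visual cortex, from retinal
    ganglion cell mosaic generation (hexagonal, jittered, correlated-jitter
    and pairwise-interacting point process mosaics) through cortical
    receptive fields and tuning extraction to thresholded and smoothed
    orientation-domain layouts.  Provides closed-form Jacobi theta-function
    solutions for the perfectly hexagonal (Moire interference) case, a full
    pinwheel-statistics pipeline (Morlet-wavelet column spacing, topological
    defect detection and charges, density, density-variability power law,
    nearest-neighbour distances), Gaussian random field ensembles with a
    normalized power-law times Gaussian band-pass spectral family, and a
    benchmark stage that scores layouts against the species-invariant
    "common design" pinwheel statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
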