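Package: shapesearch
Title: Retrieval of 3D Biological Shapes from a Few 2D Projection Images
Version: 0.1.0
Authors@R: person("Shapesearch", "Developers", email = "shapesearch@example.org",
    role = c("aut", "cre"))
Description: Builds a redundancy-reduced library of simulated 2D projection
    images from low-resolution 3D density maps (MRC format) and ranks library
    models against a small set of query projection images. Maps are normalized
    to a common grid and particle volume, converted to Gaussian mixture models
    for analytic shape superposition, clustered with Ward's method on a
    correlation-derived distance, and searched with a Z-score-based match
    score aggregated over query images. Includes a parametric synthetic-shape
    generator (spheres, ellipsoids, cylinders, dumbbells, L-blocks, bullets)
    so the whole pipeline is testable without external data, plus diagnostic
    analyses (classical multidimensional scaling of image similarity,
    per-model Pearson-correlation clustering) and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
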