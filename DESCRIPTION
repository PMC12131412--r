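Package: stmap
Title: Neural Mapping of Transcriptomes to Spatial Coordinates
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Learns a direct mapping from a cell's transcriptome to its
    spatial position from reference spatial-transcriptomics data using an
    L1-regularized fully connected network, predicts spatial origins for
    query single-cell or spatial transcriptomes, reconstructs bead-level
    expression from mapped cells by inverse-distance weighting, and ranks
    spatially variable genes by backtracking the trained network's weight
    matrices. Includes Wasserstein-distance gene filtering for batch
    effects, bivariate Moran's I consistency scoring, pairwise-distance
    benchmarking metrics with cross-validation, and a synthetic
    spatial-transcriptomics generator with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    methods,
    rhdf5,
    stats,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
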