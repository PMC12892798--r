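Package: nnmf
Title: Neighborhood Nonnegative Matrix Factorization for Spatial Transcriptomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Fits a Poisson nonnegative matrix factorization to spatial
    transcriptomics count data in which the multiplicative updates are
    interleaved with a row-normalized Gaussian-kernel smoothing of the
    per-cell weight matrix, so that spatially nearby cells share correlated
    signature activity. Includes generalized Kullback-Leibler (GKL)
    multiplicative updates, kernel length-scale estimation by grid search,
    AIC-based selection of the number of signatures, spatial batching for
    large and multi-slice datasets, TF-IDF-style gene reweighting for
    signature interpretation, K-means hard clustering of the weight vectors,
    and a synthetic-data generator with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Matrix,
    igraph,
    jsonlite,
    methods,
    stats,
    tools,
    utils,
    withr
Suggests:
    ape,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
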