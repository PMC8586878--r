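Package: sparsekm
Title: Sparse k-Means Clustering for Single-Cell Count Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: k-means clustering of sparse nonnegative count matrices, such as
    single-cell RNA-seq cells-by-genes counts, under squared Euclidean,
    Kullback-Leibler, Jensen-Shannon, Bhattacharyya and cosine dissimilarities.
    Probability-based measures use a Gamma(beta, beta) pseudo-count prior
    applied lazily, so every distance is evaluated in time proportional to the
    number of stored entries rather than the number of genes.  Seeding is by
    k-means++ with optional multi-candidate selection and localsearch++ swap
    refinement, both driven by an exponential-variate weighted sampling kernel;
    optimisation is by Lloyd's algorithm or mini-batch k-means.  Includes
    Matrix Market and raw CSR readers, highly-variable-gene preselection,
    Adjusted Rand Index evaluation, and a planted multinomial mixture
    generator for testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    graphics,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
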