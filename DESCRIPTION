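Package: dodist
Title: Distance-of-Distance Transformation for Noisy High-Dimensional Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Rewrites a dissimilarity matrix by the distance-of-distance (DoD)
    transformation: the new dissimilarity between two points is the average
    absolute difference of their original distances to the points' K-nearest-
    neighbor reference sets. In high-dimensional data containing uniformly
    scattered noise, the transform collapses the noise points into a tight
    group while preserving cluster geometry, so that neighbor-embedding
    methods such as t-SNE no longer interleave noise with clusters. Includes
    closed-form predictions for the expected shrinkage of noise-noise and
    cluster-noise distances, synthetic-data generators (Gaussian clusters plus
    uniform hypercube noise, and an idealized coincident-point variant), a
    clustering and classification evaluation harness (t-SNE embedding,
    K-means, adjusted Rand index, cross-validated KNN on precomputed
    dissimilarities), an unsupervised noise detector based on
    neighborhood-overlap rates, and delimited-text matrix input/output with a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rtsne,
    mclust,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    uwot,
    jsonlite,
    withr
Config/testthat/edition: 3
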