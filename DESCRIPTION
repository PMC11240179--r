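Package: litmap
Title: Two-Dimensional Atlases of Document Corpora with kNN Quality Metrics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Builds two-dimensional maps of large document corpora and
    quantifies their quality. Provides a MEDLINE-style ingestion and
    filtering pipeline for bibliographic records, log-scaled TF-IDF
    vectorization with truncated SVD, a t-SNE variant designed for very
    large corpora (uniform affinities on a k-nearest-neighbour graph,
    annealed early exaggeration, PCA initialization, learning rate n/12),
    and a suite of kNN-based corpus statistics: label accuracy with chance
    level, publication-year RMSE, kNN recall, corpus isolatedness,
    neighbour overlap by year, and region flag fractions. Yearly-fraction
    trend series are smoothed with penalized-spline generalized additive
    models. A synthetic corpus generator emulates topic-clustered
    abstracts, journal-keyword labels, year drift, author forenames with
    time-varying gender proportions, and retraction flags, so the whole
    pipeline can be exercised end to end without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    Rcpp,
    mgcv,
    xml2,
    yaml,
    jsonlite,
    stats,
    utils,
    methods
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
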