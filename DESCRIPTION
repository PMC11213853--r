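Package: tasc
Title: Temporally Aligned Segmentation and Clustering of Multichannel Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Iterative refinement of time-series segmentation and clustering
    for recordings of repeated behavior motifs. Candidate segments are scored
    against their cluster centroids using penalized linear temporal alignment
    (one shift and one uniform time-scale per segment), the best-scoring
    non-overlapping subset is selected by dynamic programming, unexplained
    gaps are rescanned against the centroids, and segments are re-embedded
    and re-clustered each epoch. Includes a variable-length weighted
    Euclidean distance, activity-period detection, PCA and fuzzy c-means
    defaults for embedding and clustering, segmentation and clustering
    evaluation metrics, and a ground-truthed semi-synthetic data generator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    cluster,
    e1071,
    jsonlite,
    signal,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
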