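Package: stagate
Title: Spatial Domain Identification with a Graph Attention Auto-Encoder
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Learns low-dimensional spot embeddings for spatial
    transcriptomics by combining gene expression with a spatial neighbor
    network through a graph attention auto-encoder with tied encoder and
    decoder weights. The embeddings support spatial-domain identification
    (Gaussian-mixture or Louvain clustering), expression denoising via the
    decoder reconstruction, marker-gene detection (Wilcoxon rank-sum with
    Benjamini-Hochberg control), spatial autocorrelation statistics
    (Moran's I), and 3D domain extraction across aligned consecutive
    sections. Includes a negative-binomial synthetic-tissue simulator with
    known ground truth for end-to-end validation, plain-text matrix
    readers and writers, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    Rcpp,
    igraph,
    mclust,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    ape,
    optparse,
    withr
Config/testthat/edition: 3
LinkingTo: Rcpp
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
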