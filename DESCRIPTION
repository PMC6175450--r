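Package: homeodiv
Title: Retention and Expression Divergence of Duplicated Genes in Allopolyploids
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of duplicated-gene retention and spatio-temporal
    expression divergence in allopolyploid transcriptome time series.
    Provides orthologue copy-number retention statistics with two-sample
    proportion tests, FPKM expression filtering and tissue-specificity
    contingency tests, reciprocal-best-hit homologue pair calling, a
    self-contained weighted co-expression module detector (soft-thresholded
    adjacency, topological overlap, eigengene merging), an ensemble
    self-organizing-map method that classifies regulatory divergence of
    homologue families into five patterns (redundant, distinct, gradated,
    unique, mixed) via resampling-based co-clustering probabilities and
    erf-soft-thresholded clustering coefficients, and sliding-window
    sequence conservation scanning of cis-regulatory regions. A synthetic
    data generator emulates every input so the full pipeline runs without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite,
    yaml,
    Biostrings
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph
Config/testthat/edition: 3
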