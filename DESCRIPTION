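Package: promembed
Title: Promoter Prediction from DNA Sequence Encodings and Multi-Scale Graph Embeddings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts promoter versus non-promoter DNA windows centered on a
    transcription start site. Sequences are encoded per nucleotide with
    chemical-property (NCP), running-density (ND), electron-ion interaction
    pseudopotential (EIIP) and bi-profile Bayes (BPB) features; a
    sample-similarity graph is learned by nonnegative linear-neighborhood
    reconstruction with multiplicative updates; node, community and global
    scale graph embeddings (biased random walks with skip-gram, modularity
    spectral, k-step transition-matrix factorization) augment the local
    features; and a gradient-boosted tree ensemble performs the final
    classification. Includes a synthetic promoter generator, a full metric
    suite (sensitivity, specificity, accuracy, MCC, precision, F1, AUC,
    Cohen's kappa) and a feature-ablation harness.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    igraph,
    xgboost,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
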