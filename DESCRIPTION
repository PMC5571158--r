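Package: premirna
Title: Ab Initio Pre-miRNA Hairpin Detection with Consensus Classifiers
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Detects microRNA precursor (pre-miRNA) hairpins from sequence
    alone. Provides RNA secondary-structure prediction with a pluggable
    backend (self-contained Nussinov maximum-pairing fallback, optional
    RNAfold wrapper), a registry of sequence, triplet, structural and
    thermodynamic hairpin features with per-study selection profiles,
    constructors for shuffled, suboptimal-fold and feature-space synthetic
    data sets, balanced 70/30 Monte Carlo cross-validated training of
    decision-tree, naive Bayes and support-vector classifiers, six consensus
    prediction schemes with rank-based multi-dataset evaluation and ROC
    analysis, and a sliding-window genome scanner that extracts, filters,
    parameterizes and scores candidate stem-loops with BED/FASTA/TSV output.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    rpart,
    e1071,
    nnet,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    Biostrings
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
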