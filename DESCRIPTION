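Package: galdet
Title: Selection Scans and Paralog-Specific Expression for Galactose
    Metabolism Genes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Maximum-likelihood codon substitution models (one-ratio M0,
    two-ratio branch, and branch-site models A/A1) on a fixed tree
    topology, with likelihood-ratio tests for lineage-specific shifts in
    dN/dS and Bayes empirical Bayes site posteriors for positively
    selected codons.  Companion tools cover alignment variability and
    pairwise identity statistics, premature-stop detection, bait-based
    apportioning of short reads between near-identical paralogs, TPM
    normalisation with fold-change differential-expression filtering, and
    seeded simulators for codon alignments, duplicated gene pairs, and
    sequencing reads, so the whole pipeline runs on synthetic data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    ape,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    methods,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    Matrix,
    DESeq2,
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
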