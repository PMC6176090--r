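Package: urgflow
Title: Time-Course Expression Analysis of Parasitoid Infection Cycles
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: A reusable pipeline for time-course RNA-seq analysis of
    parasitoid infection cycles: SERE-based replicate concordance QC,
    RPKM quantification, all-vs-all pairwise negative-binomial differential
    expression, classification of genes into three upregulated-gene (URG)
    stage groups by explicit log2-fold-change set logic, correlation-based
    hierarchical sub-clustering with mean/median validation, KO assignment
    by cumulative bit-score with BRITE category roll-ups, and
    Smith-Waterman reciprocal-best-hit orthology between two strains.
    Includes a synthetic-data generator that emulates the study design so
    every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    Rcpp,
    Biostrings,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
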