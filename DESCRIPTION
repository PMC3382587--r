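Package: ovamir
Title: Egg Small RNA Transcriptome Analysis: miRNA Discovery, Target
    Prediction and Expression Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A reusable, tested pipeline for small RNA sequencing analysis of
    fish eggs: adapter trimming and impurity filtering of small-RNA reads,
    collapsing to unique tags, assignment to known mature miRNAs with a
    one-mismatch tolerance, hairpin-based prediction of novel miRNAs from
    genome-mapped tags using a built-in nearest-neighbor RNA folding engine,
    homology-based partitioning of transcripts into approximate 5'UTR, coding
    and 3'UTR regions, dual-algorithm miRNA target prediction (alignment
    score with duplex free energy, and target-site accessibility ddG), and
    expression statistics for qPCR standard-curve quantification with
    multi-reference normalization, ANOVA letter groups and Kruskal-Wallis
    rank tests. Ships a fully seeded synthetic-data generator that plants
    miRNA hairpins in a toy genome, simulates an adapter-ligated small-RNA
    library, transcripts with planted target sites, and tissue-panel qPCR
    plates, so every stage is testable against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    jsonlite,
    methods,
    Rcpp,
    S4Vectors,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
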