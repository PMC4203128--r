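Package: mirforge
Title: Plant Small-RNA Processing and microRNA Discovery on Synthetic Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested, reusable pipeline for genome-wide plant microRNA
    discovery from small-RNA sequencing libraries: read quality filtering,
    adapter and poly-A trimming, collapsing to unique tags, structural
    ncRNA/repeat screening, conserved-miRNA matching, hairpin precursor
    excision and secondary-structure evaluation against a deterministic
    criteria checklist (duplex length, 2-nt 3' overhang star support,
    bifurcation-free stems, dinucleotide-shuffle significance, Dicer
    processing consistency, read support), family clustering,
    complementarity-penalty target prediction, and median-of-ratios
    expression normalization with tissue-specificity calls and qPCR
    delta-delta-CT validation. Ships a synthetic-data generator that plants
    hairpin loci in random genomes with known truth, so every stage is
    testable end-to-end without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    tibble,
    dplyr,
    tidyr,
    readr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    DESeq2,
    withr
Config/testthat/edition: 3
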