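Package: hmstseq
Title: Joint 5mC/5hmC Analysis of HMST-seq Restriction-Tag Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for HMST-seq, a three-library restriction-tag
    protocol (MspI on normal DNA, MspI on glucosylated DNA, HpaII on normal
    DNA) that deconvolves unmodified cytosine, 5-methylcytosine and
    5-hydroxymethylcytosine at CCGG sites. Provides in-silico MspI/NlaIII
    digestion and construction of the virtual tag reference, global
    rank-invariant set normalization of tag counts, exact conditional
    Poisson rate-ratio calling of significantly methylated and
    hydroxymethylated sites with Benjamini-Hochberg control, seed-and-extend
    detection of differentially methylated and hydroxymethylated regions
    between sample groups by Wilcoxon rank-sum windows, genomic feature
    annotation and TSS-distance profiles, and integration with expression
    and copy-number data to screen promoter-hypermethylated tumor-suppressor
    candidates. A fully deterministic synthetic-data generator produces
    genomes, tag counts, expression matrices and copy-number segments with
    truth tables so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    BiocGenerics,
    Biostrings,
    GenomeInfoDb,
    IRanges,
    GenomicRanges,
    S4Vectors,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
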