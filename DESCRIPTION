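Package: dualinit
Title: Dual-Initiation Promoter Analysis from CAGE 5' Ends
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Classifies CAGE transcription start sites (CTSS) by their
    initiator dinucleotide (YR versus YC) and 5' terminal oligopyrimidine
    (5'TOP) context, builds tag and consensus clusters with power-law
    tag-count normalization, calls dual-initiation promoters (DIPs),
    quantifies YC:YR transcription dynamics across sample cohorts
    (e.g. radiotherapy-responsive versus non-responsive, irradiated
    versus control), selects trajectory genes, and tests promoter motif
    enrichment with position weight matrix scanning. A synthetic-data
    module generates CAGE-like genomes, annotations and tag tables with
    known ground truth so every stage is verifiable without external
    downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    Biostrings,
    rtracklayer,
    GenomicRanges,
    BiocGenerics,
    S4Vectors,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    igraph
Config/testthat/edition: 3
RoxygenNote: 7.3.3
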