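Package: cypcensus
Title: Cytochrome P450 Family Census and Biosynthetic Gene Cluster
    Cross-Referencing for Bacterial Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A pipeline for nomenclature-rule classification of cytochrome
    P450 (CYP) proteins, per-species family and subfamily census tables,
    presence/absence profile clustering, distance-based phylogeny checks,
    cross-referencing of P450 gene loci with secondary-metabolite
    biosynthetic gene clusters (BGCs), and comparative diversity
    statistics (P450 diversity percentage and gene-cluster diversity
    percentage). Includes a synthetic-genome generator that plants P450s
    at controlled percent identity to a reference database so every stage
    can be validated against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomeInfoDb,
    GenomicRanges,
    rtracklayer,
    IRanges,
    S4Vectors,
    ape,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
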