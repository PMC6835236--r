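Package: famdup
Title: Gene Family Expansion Analysis by Duplication-Mode Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for dissecting the expansion history of large gene
    families from a chromosome-scale genome annotation. Reads gene
    coordinates from GFF3 and protein/CDS sequences from FASTA, classifies
    family proteins into domain-architecture categories from precomputed
    feature annotations, partitions family members into paralog clusters by
    pairwise sequence identity, classifies every family gene as singleton,
    tandemly duplicated, proximally duplicated or dispersed, profiles
    per-chromosome and windowed gene densities, and performs a
    counting-based per-site synonymous/nonsynonymous selection analysis on
    paralog-cluster codon alignments with a multi-method consensus merger.
    Includes a synthetic genome and alignment simulator with known
    duplication history and selection regimes for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    S4Vectors,
    rtracklayer,
    ape,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    igraph,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
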