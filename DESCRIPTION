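Package: mitopiR
Title: Identification of Mitochondria-Associated piRNAs from Small RNA
    Sequencing Data
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A pipeline for discovering mitochondria-associated
    PIWI-interacting RNAs (mito-piRNAs) in single-end small RNA
    sequencing data. Collapses reads into unique sequences with
    counts-per-million filtering, places every sequence on the nuclear
    and mitochondrial genomes with bounded-mismatch (Hamming) matching
    aware of mitochondrial circularity, derives the NU/MT/NUMT genome
    class, annotates sequences against piRNA and miRNA reference sets,
    profiles mitochondrial features and read orientation, builds
    5'-anchored piRNA families with precursor/mature roles, and infers
    retrograde, anterograde or self-contained mito-nuclear communication
    per family. Ships a fully deterministic synthetic-data generator
    with machine-readable ground truth so the whole pipeline is testable
    end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    SummarizedExperiment,
    data.table,
    jsonlite,
    yaml,
    rtracklayer
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
biocViews: Sequencing, SmallRNA, Annotation, Classification
RoxygenNote: 7.3.3
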