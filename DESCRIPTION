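Package: ldec
Title: Ligand-Dependent Estrogen Receptor Enhancer Cluster Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for ligand-dependent estrogen receptor alpha
    (ERa) enhancer clusters (LDECs) in breast cancer cells. Classifies
    two-condition ChIP-seq peak sets into persistent, transient and
    unliganded-unique binding sites; calls genomic peak clusters with a
    randomized-background permutation null; ranks stitched enhancer regions
    by signal with a tangent elbow cutoff to call super-enhancers; relates
    clusters to topologically associating domains and nascent transcription;
    normalizes 5C primer contact matrices against gene-desert controls;
    merges ChIA-PET replicates and computes anchor-degree statistics; and
    quantifies immunoFISH enrichment ratios and FRAP recovery curves. A
    seeded synthetic-data generator emulates the statistical structure of
    all inputs with ground-truth labels so every stage is testable without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    minpack.lm,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
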