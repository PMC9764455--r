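Package: phenoquant
Title: Multi-Level Phenotypic Quantification for Chromatin Perturbation Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantification pipeline for developmental phenomics of histone
    H3K4 hypomonomethylation in Drosophila. Detects transcription sites in
    multi-channel 3D confocal stacks and profiles the radial enrichment of
    chromatin marks and transcription factors around them; normalizes ChIP-seq
    coverage tracks (input subtraction, moving-average smoothing, replicate
    averaging); deconvolves population-level MALDI imaging mass spectrometry
    ion images into single-larva lipid abundance matrices with batch
    adjustment, PCA and lipid-class enrichment; computes larval locomotion
    statistics (average velocity, mover classification, head-cast detection);
    counts trichomes and measures body morphometrics; and summarizes group
    comparisons with the Student t-test conventions used throughout.
    Includes seeded synthetic-data generators for every input type with
    machine-readable ground truth, so the full pipeline is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    EBImage,
    rtracklayer,
    GenomicRanges,
    IRanges,
    jsonlite,
    tiff
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
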