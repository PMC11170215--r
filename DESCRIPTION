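Package: linkreads
Title: Platform-Agnostic Linked-Read Processing, Simulation, and
    Metagenomic Quantification
Version: 0.1.0
Authors@R:
    person("Sam", "Okoye", email = "sokoye.dev@example.org", role = c("aut", "cre"))
Description: Tools for linked-read sequencing data from the 10x Genomics,
    stLFR and TELL-seq platforms: conversion of raw reads into a unified
    barcoded FASTQ representation (BX tag), barcode sequencing-error
    correction with or without a whitelist, simulation of linked-read
    libraries with ground-truth fragments and alignments, reconstruction
    of long DNA fragments from barcode-aware alignments together with
    library quality statistics (C_R, C_F, N_F/P, mu_FL, Wmu_FL), tiered
    window-based metagenomic taxonomic quantification with explicit
    multimapping weights, metagenomic SNV filtering, longitudinal
    strain-frequency-change detection, and rule-based MAG quality
    classification.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    tools,
    IRanges,
    Biostrings,
    Rsamtools,
    VariantAnnotation,
    S4Vectors,
    SummarizedExperiment,
    BiocGenerics,
    GenomeInfoDb
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
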