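Package: uORFtools
Title: Annotation of Upstream Open Reading Frames and Their Variants
Version: 0.9.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Toolkit for upstream open reading frame (uORF) analysis on spliced
    transcripts: conversion of translation initiation sites (TISs) into ORFs and
    their classification into non-overlapping uORFs, overlapping uORFs, CDS
    extensions and CDS truncations; codon-independent Kozak context scoring of
    ATG and near-cognate start codons; annotation of genetic variants located in
    uORFs with a four-way classification of their impact on the main coding
    sequence (main_CDS_unaffected, overlap_removal, N-terminal_extension,
    out_of_frame_overlap); reconciliation of uORF catalogs into a
    high-confidence set; and a gradient-boosted translation initiation site
    classifier with one-hot sequence encoding, initiating-ribosome signal
    features, gene-aware data splitting and per-codon evaluation. A
    deterministic synthetic-fixture generator provides genomes, transcript
    models, uORFs of every class, signal tracks and variant suites with known
    expected annotations.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    rtracklayer,
    SummarizedExperiment,
    VariantAnnotation,
    data.table,
    jsonlite,
    xgboost
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
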