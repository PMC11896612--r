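Package: artenh
Title: Cross-Species Identification and Characterization of Arterial Endothelial Enhancers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for characterizing arterial endothelial enhancers from
    chromatin-mark interval tracks, sequence motifs, and transcription-factor
    binding peaks. Calls putative enhancers under a cross-species evidence rule
    (at least one enhancer mark in both mouse and human endothelial cells, with
    a relaxed two-mouse-mark rule for genes poorly transcribed in human cells),
    scans enhancer cores for transcription-factor family motifs with a
    three-tier conservation classification against multi-species alignments,
    detects FOX:ETS composite elements, derives per-enhancer binding calls and
    peak-set co-occupancy statistics, classifies transgenic reporter assay
    outcomes with a strict greater-than-5-percent activity rule, and
    cross-tabulates motif and binding status by enhancer class. Includes a
    synthetic two-species locus simulator with planted ground truth so every
    stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    Biostrings,
    methods,
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
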