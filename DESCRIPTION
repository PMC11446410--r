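Package: hcrkit
Title: Split-Initiator Probe Design and Spot Colocalization for HCR v3 RNA
    Imaging
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Design pipeline for third-generation hybridization chain
    reaction (HCR v3) split-initiator probe sets: candidate tiling along a
    target transcript, nearest-neighbor melting-temperature and GC
    filtering, off-target screening against a transcriptome (internal
    k-mer seed-and-extend backend or external 'blastn'), non-overlapping
    probe selection, split-initiator pair assembly with simulated
    hybridization validation, and order-sheet / probe-map reporting.
    Includes exon-junction-aware FASTA input handling, a dual-direction
    within-radius spot colocalization statistic for comparing detection
    methods, and deterministic synthetic-fixture generators for targets,
    decoy transcriptomes and paired 3-D spot fields.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
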