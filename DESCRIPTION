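Package: srnasig
Title: Small RNA Biogenesis Signatures, Locus Annotation and Library
    Simulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for surveying small-RNA biogenesis pathways in
    genome-aligned sRNA-seq libraries.  Detects Dicer-product (siRNA-like)
    duplex read pairs by their 2-nt 3' overhang geometry, computes piRNA
    Ping-Pong (10-nt 5' overlap) and Zucchini phasing (1U distance-1)
    signature histograms with focal-bin z-scores, annotates
    small-RNA-expressing loci by coverage with feature merging and RPM
    thresholding (including the merge-distance by read-depth sweep used to
    pick an operating point), classifies loci by read-size profile, and
    builds per-locus count matrices and PCA coordinates across libraries.
    A synthetic-data generator plants loci of known biogenesis class in toy
    genomes and emits a ground-truth manifest, so every stage is testable
    without external sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    graphics,
    IRanges,
    jsonlite,
    Rsamtools,
    S4Vectors,
    stats,
    tools,
    utils,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
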