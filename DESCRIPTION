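Package: tarseq
Title: Two-Sample Whole-Transcriptome RNA-Seq Comparison with Novel
    Transcription Discovery
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Post-alignment analysis of a pair of strand-specific,
    rRNA-depleted RNA-Seq libraries (e.g. a trisomic versus a euploid
    sample) without replicates. Revises a gene annotation into a
    non-overlapping element/locus model, counts uniquely assigned reads by
    their 5' start, augments locus counts with splice-junction reads,
    computes RPKM and five expression categories, derives stranded
    intronic/intergenic regions and refines them into transcriptionally
    active regions (TARs) by windowed read-density segmentation, detects
    UTR extensions in fixed flanking windows, scans TARs for open reading
    frames, calls alternative-splicing events and sample-specific
    junctions from a combinatorial exon-junction library, and classifies
    differential-expression evidence from three exact two-library count
    tests. Includes a seeded synthetic-data generator with a planted truth
    set for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    Biostrings,
    rtracklayer,
    data.table,
    jsonlite,
    stats,
    utils,
    methods
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
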