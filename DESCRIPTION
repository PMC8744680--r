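Package: recaptss
Title: Transcription Start Site Calling and Classification for
    ReCappable-Seq Libraries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Downstream analysis of ReCappable-seq experiments: reduces
    aligned reads from matched enriched, CIP-pretreated and unenriched
    control libraries to strand-aware single-nucleotide 5' end tag counts,
    calls candidate transcription start sites (TSSs) by tags-per-million
    thresholds, filters them against the unenriched control and classifies
    high-confidence TSSs into Pol II and non-Pol II sets from their
    CIP sensitivity. Includes gene assignment against GTF annotation,
    locus clustering of unannotated TSSs, flanking base-composition and
    anchor-relative positioning profiles, precision/sensitivity
    benchmarking against reference TSS sets, transcript body coverage,
    and a seeded read simulator that emits aligned libraries with a
    ground-truth TSS table for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicAlignments,
    GenomicRanges,
    IRanges,
    Rsamtools,
    S4Vectors,
    graphics,
    rtracklayer,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
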