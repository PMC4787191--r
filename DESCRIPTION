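Package: lncCurate
Title: Curation, Discovery and Annotation of Long Non-Coding RNAs
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for building a curated, non-redundant catalogue of long
    non-coding RNAs (lncRNAs) from heterogeneous annotation sources and
    RNA-seq derived transcript models.  Implements explicit redundancy rules
    for merging lncRNA sets (same-locus, 50 percent and 90 percent overlap
    rules with an exon-count exception), a novel-lncRNA filter funnel
    (intergenicity, length, coding potential, ribosomal RNA exclusion, read
    support, sense overlap) with full per-stage accounting, genomic
    classification of lncRNAs relative to coding genes (intergenic, exonic,
    intronic, each sense/antisense), RPKM quantification with expressed and
    poly(A)-minus calls from dual-chemistry libraries, chromatin-signature
    assignment (H3K4me3, H3K36me3, Pol II, the K4-K36 signature) from peak
    intervals, CAGE-based 5' completeness, RT-qPCR detection calls, and a
    seeded synthetic-data generator that plants ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    IRanges,
    jsonlite,
    stats,
    utils
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
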