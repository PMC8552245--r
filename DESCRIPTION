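Package: dreamtargets
Title: Integrative ChIP-seq and RNA-seq Classification of DREAM Complex Targets
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end, testable pipeline for classifying transcription-factor
    targets of the DREAM repressive complex in C. elegans from ChIP-seq and
    RNA-seq derived inputs. Detects peaks as concave regions of smoothed
    coverage, filters them by replicate reproducibility, assigns peaks to genes
    through promoter-anchored windows, tests differential expression and
    differential binding with a negative-binomial Wald test, classifies genes
    into direct, LIN-36-shared and LIN-15B-shared target classes, quantifies
    gene-body H2A.Z and promoter H3K9me2 marks, scans peak sequences with
    position weight matrices using exact p-values, and ships a synthetic-data
    generator with planted ground truth so every stage is verifiable without
    external downloads.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    data.table,
    jsonlite,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Biostrings,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    optparse,
    DESeq2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
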