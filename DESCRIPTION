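Package: sepal
Title: Super-Enhancer Discovery from Plant Accessible Chromatin Landscapes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies putative super-enhancers (SEs) in plant genomes as the
    top length quantile of clustered nonpromoter accessible chromatin regions
    (ACRs), starting from DNase-seq style read-start tracks or per-sample peak
    calls. Provides kernel-density peak calling with empirical-FDR retention,
    multi-sample ACR atlas construction with promoter classification, SE
    selection with cognate-gene assignment and genomic-position classes,
    gene-density and TAD/loop context statistics with empirical permutation
    tests, transcription-factor occupancy and odds-ratio enrichment,
    synteny-anchored cross-species conservation scoring by iterated local
    alignment, and presence/absence genotyping of known insertions from
    junction-spanning read pairs. A seedable synthetic-data generator emits
    every input format with truth tables so the whole pipeline is testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    Biostrings,
    rtracklayer,
    jsonlite,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
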