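Package: polpause
Title: RNA Polymerase II Promoter-Proximal Pausing and Promoter Occupancy Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Integrative analysis of RNA polymerase II promoter-proximal
    pausing and transcription-factor promoter occupancy from ChIP-seq
    peak calls and coverage tracks. Computes per-gene pausing indices
    (TSS-region over gene-body signal density), positional
    cross-correlation profiles between peak sets, annotation of peaks
    over genomic features, promoter-binding stratification of genes,
    and wild-type versus knockdown comparisons of pausing and
    expression using Mann-Whitney-Wilcoxon tests. Includes a
    deterministic synthetic-data generator with planted ground truth
    (pausing ratios, binding labels, differential-expression labels)
    so every stage of the pipeline is testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
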