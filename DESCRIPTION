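Package: epiclock
Title: Epigenetic Age Prediction from Nanopore Methylation Frequencies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: An end-to-end epigenetic clock pipeline for long-read
    methylation data in livestock. Reads per-site CpG methylation
    frequency tables (the nanopolish/f5c dialect), aggregates them into
    binarized 100 bp window calls, applies call-rate and variability
    filters, builds methylation relationship matrices (MRM = XX'/m),
    predicts age by REML/BLUP mixed models with grouped cross-validation
    (MeBLUP), and tests gene-level methylation-age associations with
    Satterthwaite p-values, direction-concordance rules and binomial
    enrichment. Includes a synthetic-data generator with known ground
    truth (age-dependent clock sites, herd confounding,
    coverage-dependent missingness) for validation of the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    data.table,
    jsonlite,
    yaml,
    S4Vectors,
    IRanges,
    GenomicRanges,
    rtracklayer,
    lme4,
    lmerTest
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
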