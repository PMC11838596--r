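Package: laconcord
Title: Concordance of Interval- and SNP-Level Local Ancestry Calls with
    Admixture Mapping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for comparing two local ancestry inference datasets for
    an admixed cohort: an interval-based call set (RFMix-style diploid
    ancestry counts over genomic intervals) and a SNP-level call set
    (FLARE-style per-variant ancestry calls with allele-frequency and
    imputation-quality fields). Provides a synthetic-cohort generator
    (Poisson ancestry-switch tracts, two noisy observation channels on two
    genome builds, design covariates, kinship, and phenotypes), readers and
    writers for the interchange formats, QC filtering, block-map liftover
    with discard accounting, global-ancestry agreement, per-locus Pearson
    correlation profiling, annotation-proximity enrichment of discordant
    loci with matched high-correlation controls, and admixture mapping via
    REML-fitted linear mixed models with household, census-block and
    kinship random effects followed by per-locus score tests, simplified
    multiple-testing thresholds, and discovery/replication comparison
    tables.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    SummarizedExperiment,
    VariantAnnotation,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    lme4,
    withr,
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
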