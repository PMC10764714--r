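Package: imputeval
Title: Evaluation and Combination of Genotype Imputation Runs
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Evaluate and combine genotype imputation runs. Implements the
    chance-corrected Imputation Quality Score (IQS) computed from posterior
    genotype probabilities against a truth set, stratified per individual,
    per variant, per genomic region and per minor-allele-frequency bin; a
    per-genotype "most confident vote" merge of two imputation runs with a
    configurable priority margin, together with Accord/Discord concordance
    bookkeeping; switch-error-rate estimation from repeated phasing runs by
    majority-vote consensus; aggregation of pairwise identity-by-descent
    segments into group-level sharing matrices split by segment length; and
    a synthetic-data generator (Hardy-Weinberg truth genotypes, calibrated
    posterior trios with group- and frequency-dependent accuracy,
    seed-perturbed phasings with a known switch rate, group-structured IBD
    segments) that makes the whole pipeline testable without cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    vcfR,
    rtracklayer,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
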