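Package: blendr
Title: Cell-Type Composition Indices for Bulk Brain Transcriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts the relative cell-type balance of macro-dissected brain
    transcriptomic samples from curated cell-type-specific marker genes.
    Expression rows are z-scored across samples, collapsed from transcripts to
    genes, and averaged over each reference publication's marker set to give
    publication-specific cell-type indices; these are consolidated into ten
    primary cortical cell-type indices after removing genes claimed by more
    than one category. Includes a ground-truthed simulator (purified profiles,
    titration mixtures, covariate-driven cohorts), covariate scans of the
    indices with fixed-effects meta-analysis across studies, and per-gene
    differential-expression model comparison (with and without cell-type
    covariates) evaluated by information criteria, replication rates, and
    Fisher exact enrichment.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    metafor,
    jsonlite,
    optparse,
    knitr
Config/testthat/edition: 3
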