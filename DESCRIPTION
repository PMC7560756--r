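Package: svpop
Title: Structural-Variant Population Genomics with Curation-Based
    Filtering, Permutation F(ST) Outlier Scans and Ohnolog Enrichment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for population-scale structural-variant (SV) analysis in
    species with a duplicated genome history, modelled on the Atlantic
    salmon SV landscape. Provides reliability filtering of SV calls
    (coverage-derived complex-region exclusion, reciprocal-overlap
    deduplication, visual-curation false discovery rate accounting),
    amplicon-based genotype validation and concordance reporting, per-SV
    Weir-Cockerham F(ST) with a label-permutation outlier procedure,
    enrichment tests for SV overlap with whole-genome-duplication
    (ohnolog) gene pairs, expression-correlation resampling nulls,
    tissue-specificity enrichment of outlier-linked genes, and a fully
    seeded synthetic-data generator that reproduces the statistical
    structure every stage assumes, so the whole pipeline is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    IRanges,
    jsonlite,
    rlang,
    S4Vectors,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    vcfR,
    withr,
    yaml
Suggests:
    rtracklayer,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
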