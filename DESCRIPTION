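Package: sexhet
Title: Discovery and Functional Enrichment of Sex-Heterogeneous SNPs from
    Sex-Stratified GWAS Summary Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Identifies autosomal SNPs with sexually dimorphic effects
    (sex-heterogeneous, "sex-het", SNPs) from female- and male-stratified
    GWAS summary statistics using Cochran's Q heterogeneity tests, combines
    evidence across traits by correlated fixed-effects meta-analysis of
    heterogeneity Z-scores, and reduces the result to an independent catalog
    by greedy LD clumping. Quantifies enrichment of the catalog in disease
    and trait association signal, regulatory annotations, methylation and
    predicted-expression QTL maps, gene annotations, and gene sets, against
    permuted sets of sex-homogeneous SNPs matched on minor allele frequency
    and marginal-effect rank. Ships a synthetic-data generator with planted
    sex-heterogeneous effects, LD blocks and controllable pleiotropy so the
    whole pipeline is testable at desk scale.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    data.table,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    fgsea,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'utils.R'
    'AllClasses.R'
    'AllGenerics.R'
    'matched-null.R'
    'enrichment.R'
    'gene-annotation.R'
    'het-stats.R'
    'ld-clump.R'
    'multitrait-meta.R'
    'ora.R'
    'sumstats-io.R'
    'synthetic-data.R'
    'pipeline.R'
    'sexhet-package.R'
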