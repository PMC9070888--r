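#' @include utils.R
NULL

.SUMSTATS_COLS <- c("snp_id", "chrom", "pos", "effect_allele", "other_allele",
                    "eaf", "beta", "se", "pvalue", "n")

#' Sumstats: one trait, one stratum of GWAS summary statistics
#'
#' Container for the association results of a single trait in a single
#' stratum (female, male, or combined-sex), with allele-aware effect sizes.
#' Rows violating the class invariants (allele frequency outside `[0,1]`,
#' non-positive standard error, p-value outside `(0,1]`, identical alleles,
#' duplicated SNP ids) are dropped at construction and counted.
#'
#' @slot data `data.frame` with columns `snp_id`, `chrom`, `pos` (1-based),
#'   `effect_allele`, `other_allele`, `eaf`, `beta`, `se`, `pvalue`, `n`.
#' @slot trait Trait label.
#' @slot stratum One of `"female"`, `"male"`, `"combined"` or `""`.
#' @slot nDropped Number of rows dropped during validation.
#' @export
setClass("Sumstats",
         slots = c(data = "data.frame", trait = "character",
                   stratum = "character", nDropped = "integer"))

setValidity("Sumstats", function(object) {
  d <- object@data
  miss <- setdiff(.SUMSTATS_COLS, names(d))
  if (length(miss)) return(paste("missing columns:", paste(miss, collapse = ", ")))
  if (anyDuplicated(d$snp_id)) return("duplicate snp_id")
  if (nrow(d)) {
    if (any(d$eaf < 0 | d$eaf > 1)) return("eaf outside [0,1]")
    if (any(d$se <= 0)) return("non-positive se")
    if (any(d$pvalue <= 0 | d$pvalue > 1)) return("pvalue outside (0,1]")
    if (any(d$effect_allele == d$other_allele)) return("identical alleles")
  }
  TRUE
})

#' Construct a Sumstats object, dropping invalid rows
#'
#' @param data `data.frame` with the canonical summary-statistic columns.
#' @param trait,stratum Labels stored with the table.
#' @param drop Drop (and count) rows violating invariants instead of erroring.
#' @return A [Sumstats-class] object.
#' @export
Sumstats <- function(data, trait = "", stratum = "", drop = TRUE) {
  .stopifnotCols(data, .SUMSTATS_COLS, "summary statistics")
  d <- as.data.frame(data)[, .SUMSTATS_COLS]
  d$snp_id <- as.character(d$snp_id)
  d$chrom <- as.character(d$chrom)
  d$effect_allele <- toupper(as.character(d$effect_allele))
  d$other_allele <- toupper(as.character(d$other_allele))
  for (col in c("pos", "eaf", "beta", "se", "pvalue", "n")) {
    d[[col]] <- suppressWarnings(as.numeric(d[[col]]))
  }
  n0 <- nrow(d)
  if (drop) {
    ok <- complete.cases(d[c("snp_id", "pos", "eaf", "beta", "se", "pvalue")]) &
      d$eaf >= 0 & d$eaf <= 1 & d$se > 0 &
      d$pvalue > 0 & d$pvalue <= 1 &
      d$effect_allele != d$other_allele &
      !duplicated(d$snp_id)
    d <- d[ok, , drop = FALSE]
    if (n0 - nrow(d) > 0) {
      .sexhetLog(sprintf("Sumstats(%s/%s): dropped %d of %d rows failing validation",
                         trait, stratum, n0 - nrow(d), n0))
    }
  }
  rownames(d) <- NULL
  new("Sumstats", data = d, trait = trait, stratum = stratum,
      nDropped = as.integer(n0 - nrow(d)))
}

#' PairedSumstats: harmonized female/male records for one trait
#'
#' Per-SNP joined female and male summary statistics on a shared
#' effect-allele orientation, as produced by [harmonizePair()].
#'
#' @slot data `data.frame` with shared columns (`snp_id`, `chrom`, `pos`,
#'   `effect_allele`, `other_allele`, `maf`, `n_total`) and per-stratum
#'   columns suffixed `_f` / `_m` (`eaf`, `beta`, `se`, `pvalue`, `n`).
#' @slot trait Trait label.
#' @slot nDropped Named integer: counts of SNPs dropped as strand-ambiguous
#'   or allele-mismatched.
#' @export
setClass("PairedSumstats",
         slots = c(data = "data.frame", trait = "character",
                   nDropped = "integer"))

setValidity("PairedSumstats", function(object) {
  need <- c("snp_id", "chrom", "pos", "effect_allele", "other_allele",
            "maf", "n_total", paste0(rep(c("eaf", "beta", "se", "pvalue", "n"), 2),
                                     rep(c("_f", "_m"), each = 5)))
  miss <- setdiff(need, names(object@data))
  if (length(miss)) return(paste("missing columns:", paste(miss, collapse = ", ")))
  if (anyDuplicated(object@data$snp_id)) return("duplicate snp_id")
  TRUE
})

#' LDProvider: pairwise linkage-disequilibrium lookup
#'
#' Sparse symmetric r-squared lookup backed by per-SNP neighbor lists.
#' `r2(a, a) = 1`; pairs absent from the store (including cross-chromosome
#' pairs) have `r2 = 0`.
#'
#' @slot neighbors Environment keyed by SNP id; each entry is a
#'   `data.frame(other, r2)`.
#' @export
setClass("LDProvider", slots = c(neighbors = "environment"))

#' SexHetCatalog: independent sex-heterogeneous tag SNPs
#'
#' The clumped catalog of sex-het SNPs: pairwise LD r-squared below the
#' clumping threshold, sorted by ascending best Cochran's Q p-value.
#'
#' @slot data `data.frame` with at least `snp_id`, `chrom`, `pos`, `maf`,
#'   `best_p_q`; typically also `leading_trait`, `direction`, `mechanism`,
#'   `provenance`.
#' @slot r2Threshold Clumping r-squared threshold used.
#' @export
setClass("SexHetCatalog",
         slots = c(data = "data.frame", r2Threshold = "numeric"))

setValidity("SexHetCatalog", function(object) {
  d <- object@data
  miss <- setdiff(c("snp_id", "chrom", "pos", "maf", "best_p_q"), names(d))
  if (length(miss)) return(paste("missing columns:", paste(miss, collapse = ", ")))
  if (anyDuplicated(d$snp_id)) return("duplicate snp_id")
  if (is.unsorted(d$best_p_q)) return("not sorted by best_p_q")
  TRUE
})

#' Construct a SexHetCatalog
#'
#' @param data `data.frame` of tag SNPs (see [SexHetCatalog-class]).
#' @param r2Threshold Clumping threshold recorded with the catalog.
#' @return A [SexHetCatalog-class] object, sorted by `best_p_q`.
#' @export
SexHetCatalog <- function(data, r2Threshold = 0.2) {
  d <- as.data.frame(data)
  .stopifnotCols(d, c("snp_id", "chrom", "pos", "maf", "best_p_q"), "catalog")
  d <- d[order(d$best_p_q, d$chrom, d$pos, d$snp_id), , drop = FALSE]
  rownames(d) <- NULL
  new("SexHetCatalog", data = d, r2Threshold = r2Threshold)
}

#' MatchedNullSet: one permuted set of matched sex-homogeneous SNPs
#'
#' One SNP per catalog entry, drawn uniformly among eligible pool SNPs
#' matched on minor allele frequency and marginal-effect rank (see
#' [sampleMatchedSet()]).
#'
#' @slot snps Character vector of sampled SNP ids, aligned with the catalog.
#' @slot meta `data.frame` with per-entry `catalog_snp`, `maf_delta`,
#'   `rank_delta` and `relaxed` (0 = matched within the stated tolerances;
#'   k > 0 = tolerances doubled k times; -1 = nearest-neighbor fallback).
#' @slot seed Seed of the per-set RNG stream.
#' @export
setClass("MatchedNullSet",
         slots = c(snps = "character", meta = "data.frame", seed = "integer"))

#' EnrichmentResult: observed overlap statistic with its null summary
#'
#' @slot nOverlap SNPs shared between the catalog and the target.
#' @slot observedStat Observed statistic on the percent scale (percent of
#'   overlapping SNPs with association p below alpha, or percent overlap).
#' @slot expectedStat Null expectation on the same scale.
#' @slot expectedCount Expected count (`alpha * nOverlap`) where applicable.
#' @slot chi2P Analytic p-value (1-df goodness-of-fit), `NA` if not computed.
#' @slot empP Empirical p-value against matched null sets, `NA` if no nulls.
#' @slot nullStats Per-null-set statistics used for `empP`.
#' @slot items Free-form list of per-item extras (unique probe/eGene counts,
#'   per-SNP item ranges, depletion empirical p, ...).
#' @export
setClass("EnrichmentResult",
         slots = c(nOverlap = "integer", observedStat = "numeric",
                   expectedStat = "numeric", expectedCount = "numeric",
                   chi2P = "numeric", empP = "numeric",
                   nullStats = "numeric", items = "list"))

.EnrichmentResult <- function(nOverlap, observedStat, expectedStat,
                              expectedCount = NA_real_, chi2P = NA_real_,
                              empP = NA_real_, nullStats = numeric(0),
                              items = list()) {
  new("EnrichmentResult", nOverlap = as.integer(nOverlap),
      observedStat = observedStat, expectedStat = expectedStat,
      expectedCount = expectedCount, chi2P = chi2P, empP = empP,
      nullStats = nullStats, items = items)
}

#' GeneModels: minimal gene-model container for SNP annotation
#'
#' @slot genes `GRanges` of gene bodies with an mcols column `gene_id`.
#' @slot exons `GRanges` of exons with `gene_id` (may be empty).
#' @slot utrs `GRanges` of untranslated regions with `gene_id` (may be empty).
#' @export
setClass("GeneModels",
         slots = c(genes = "GRanges", exons = "GRanges", utrs = "GRanges"))

#' Construct a GeneModels object
#'
#' @param genes `GRanges` of gene bodies; `mcols(genes)$gene_id` required.
#' @param exons,utrs Optional `GRanges` with `gene_id`. Without exon
#'   structure every genic SNP classifies as intronic.
#' @return A [GeneModels-class] object.
#' @export
GeneModels <- function(genes, exons = NULL, utrs = NULL) {
  if (is.null(mcols(genes)$gene_id)) stop("genes must carry a gene_id column")
  empty <- GRanges()
  mcols(empty)$gene_id <- character(0)
  new("GeneModels", genes = genes,
      exons = if (is.null(exons)) empty else exons,
      utrs = if (is.null(utrs)) empty else utrs)
}
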