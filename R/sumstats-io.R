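#' @include AllClasses.R
NULL

#' Column-name dialects for summary-statistic files
#'
#' Returns a named character vector mapping the canonical column names used
#' throughout the package to the column headers found in a file. Presets
#' mirror common consortium release headers.
#'
#' @param preset `"default"` (canonical names), `"giant"` or `"neale"`.
#' @return Named character vector `canonical -> file column`.
#' @export
#' @examples
#' sumstatsDialect("giant")
sumstatsDialect <- function(preset = c("default", "giant", "neale")) {
  preset <- match.arg(preset)
  switch(preset,
    default = c(snp_id = "snp_id", chrom = "chrom", pos = "pos",
                effect_allele = "effect_allele", other_allele = "other_allele",
                eaf = "eaf", beta = "beta", se = "se", pvalue = "pvalue", n = "n"),
    giant = c(snp_id = "MarkerName", chrom = "Chr", pos = "Pos",
              effect_allele = "Allele1", other_allele = "Allele2",
              eaf = "FreqAllele1HapMapCEU", beta = "b", se = "se",
              pvalue = "p", n = "N"),
    neale = c(snp_id = "variant", chrom = "chr", pos = "pos",
              effect_allele = "alt", other_allele = "ref",
              eaf = "minor_AF", beta = "beta", se = "se",
              pvalue = "pval", n = "n_complete_samples"))
}

#' Read a summary-statistics file
#'
#' Reads a tab-delimited (optionally gzip-compressed) association file,
#' renames columns according to a dialect, and validates it into a
#' [Sumstats-class] object. Rows failing the class invariants are dropped
#' and counted; a missing mandatory column is a hard error.
#'
#' @param path File path.
#' @param dialect Named character vector from [sumstatsDialect()] (or
#'   user-supplied), mapping canonical names to file headers.
#' @param trait,stratum Labels stored with the table.
#' @return A [Sumstats-class] object.
#' @export
readSumstats <- function(path, dialect = sumstatsDialect("default"),
                         trait = "", stratum = "") {
  if (!file.exists(path)) stop("file not found: ", path)
  dt <- if (grepl("\\.gz$", path)) {
    read.table(gzfile(path), header = TRUE, sep = "\t",
               stringsAsFactors = FALSE)
  } else {
    fread(path, sep = "\t", header = TRUE, data.table = FALSE,
          showProgress = FALSE)
  }
  miss <- setdiff(unname(dialect), names(dt))
  if (length(miss)) {
    stop(sprintf("'%s' is missing mandatory column(s): %s",
                 path, paste(miss, collapse = ", ")))
  }
  out <- dt[, unname(dialect)]
  names(out) <- names(dialect)
  Sumstats(out, trait = trait, stratum = stratum)
}

#' Write a Sumstats table as tab-delimited text
#'
#' @param x A [Sumstats-class] object.
#' @param path Output path (`.gz` suffix triggers gzip compression).
#' @return `path`, invisibly.
#' @export
writeSumstats <- function(x, path) {
  stopifnot(is(x, "Sumstats"))
  fwrite(x@data, path, sep = "\t", compress = "auto")
  invisible(path)
}

#' Harmonize female and male summary statistics onto one allele orientation
#'
#' Joins the two strata on SNP id, aligns the male records to the female
#' effect allele (swapped alleles: beta negated, eaf complemented), drops
#' strand-ambiguous SNPs (A/T, C/G pairs, whose orientation cannot be
#' resolved from summary data) and allele-mismatched SNPs, and populates
#' `maf` (minor allele frequency from the female stratum) and `n_total`.
#'
#' @param female,male [Sumstats-class] objects for the two strata.
#' @param trait Trait label (defaults to the female table's label).
#' @return A [PairedSumstats-class] object.
#' @export
harmonizePair <- function(female, male, trait = female@trait) {
  stopifnot(is(female, "Sumstats"), is(male, "Sumstats"))
  f <- female@data
  m <- male@data
  common <- intersect(f$snp_id, m$snp_id)
  if (!length(common)) stop("no SNPs shared between female and male tables")
  f <- f[match(common, f$snp_id), ]
  m <- m[match(common, m$snp_id), ]

  ambiguous <- .isAmbiguousPair(f$effect_allele, f$other_allele) |
    .isAmbiguousPair(m$effect_allele, m$other_allele)
  same <- f$effect_allele == m$effect_allele & f$other_allele == m$other_allele
  swapped <- f$effect_allele == m$other_allele & f$other_allele == m$effect_allele
  keep <- !ambiguous & (same | swapped)

  nAmb <- sum(ambiguous)
  nMis <- sum(!ambiguous & !(same | swapped))
  if (nAmb + nMis > 0) {
    .sexhetLog(sprintf("harmonizePair(%s): dropped %d strand-ambiguous and %d allele-mismatched SNPs",
                       trait, nAmb, nMis))
  }
  f <- f[keep, ]
  m <- m[keep, ]
  flip <- swapped[keep]
  m$beta[flip] <- -m$beta[flip]
  m$eaf[flip] <- 1 - m$eaf[flip]

  if (!nrow(f)) stop("empty intersection after harmonization")
  d <- data.frame(
    snp_id = f$snp_id, chrom = f$chrom, pos = f$pos,
    effect_allele = f$effect_allele, other_allele = f$other_allele,
    eaf_f = f$eaf, beta_f = f$beta, se_f = f$se, pvalue_f = f$pvalue, n_f = f$n,
    eaf_m = m$eaf, beta_m = m$beta, se_m = m$se, pvalue_m = m$pvalue, n_m = m$n,
    stringsAsFactors = FALSE)
  d$maf <- pmin(d$eaf_f, 1 - d$eaf_f)
  d$n_total <- d$n_f + d$n_m
  rownames(d) <- NULL
  new("PairedSumstats", data = d, trait = trait,
      nDropped = c(ambiguous = nAmb, mismatched = nMis))
}

#' Read a GMT gene-set file
#'
#' @param path Path to a GMT file (set name, description, member genes).
#' @return Named list of character vectors of gene ids.
#' @export
readGmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  fgsea::gmtPathways(path)
}

#' Write gene sets as GMT
#'
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @param description Description field (second GMT column), recycled.
#' @return `path`, invisibly.
#' @export
writeGmt <- function(sets, path, description = "na") {
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], description, sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a BED file of genomic intervals
#'
#' Standard 0-based half-open BED is converted to the 1-based closed
#' coordinates used for SNP positions (a BED row `chr1 10 20` contains
#' 1-based positions 11..20).
#'
#' @param path Path to a BED file.
#' @return A `GRanges` object.
#' @export
readBed <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  rtracklayer::import(path, format = "BED")
}

#' Write intervals as BED
#' @param gr A `GRanges` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeBed <- function(gr, path) {
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Read a QTL map (meQTL or predicted-eQTL table)
#'
#' Tab-delimited with header. meQTL maps carry columns `snp`, `cpg`, `p`,
#' `tissue`; predicted-eQTL (Pr-eQTL) maps carry `snp`, `egene`, `tissue`.
#' Malformed rows (empty ids, unparseable p) are dropped with a warning.
#'
#' @param path File path.
#' @param type `"meqtl"` or `"preqtl"`.
#' @return `data.frame` with the validated columns.
#' @export
readQtlMap <- function(path, type = c("meqtl", "preqtl")) {
  type <- match.arg(type)
  if (!file.exists(path)) stop("file not found: ", path)
  d <- fread(path, sep = "\t", header = TRUE, data.table = FALSE,
             showProgress = FALSE)
  cols <- if (type == "meqtl") c("snp", "cpg", "p", "tissue") else
    c("snp", "egene", "tissue")
  .stopifnotCols(d, cols, path)
  d <- d[, cols]
  idcol <- if (type == "meqtl") "cpg" else "egene"
  ok <- !is.na(d$snp) & nzchar(d$snp) & !is.na(d[[idcol]]) & nzchar(d[[idcol]])
  if (type == "meqtl") {
    d$p <- suppressWarnings(as.numeric(d$p))
    ok <- ok & !is.na(d$p) & d$p > 0 & d$p <= 1
  }
  if (any(!ok)) {
    warning(sprintf("readQtlMap: dropped %d malformed rows from %s",
                    sum(!ok), path))
    d <- d[ok, ]
  }
  rownames(d) <- NULL
  d
}

#' Read a two-column pLI table
#'
#' @param path Tab-delimited file with columns gene id and pLI score; a
#'   header line is auto-detected.
#' @return Named numeric vector of pLI scores in `[0,1]`.
#' @export
readPli <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  d <- fread(path, sep = "\t", header = "auto", data.table = FALSE,
             showProgress = FALSE)
  if (ncol(d) < 2) stop("pLI table must have two columns: ", path)
  gene <- as.character(d[[1]])
  pli <- suppressWarnings(as.numeric(d[[2]]))
  ok <- nzchar(gene) & !is.na(pli) & pli >= 0 & pli <= 1
  if (any(!ok)) {
    warning(sprintf("readPli: dropped %d malformed rows from %s", sum(!ok), path))
  }
  setNames(pli[ok], gene[ok])
}
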