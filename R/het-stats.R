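#' @include AllClasses.R
NULL

#' Cochran's Q heterogeneity test between female and male effects
#'
#' For two strata, `Q = (beta_f - beta_m)^2 / (se_f^2 + se_m^2)`, chi-square
#' distributed with 1 df under homogeneity. All arguments are vectorized.
#'
#' @param betaF,seF,betaM,seM Effect estimates and standard errors for the
#'   female and male strata.
#' @return List with numeric vectors `q` and `p`.
#' @export
#' @examples
#' cochranQ(0.5, 0.1, 0.2, 0.1)  # q = 4.5, p ~ 0.0339
cochranQ <- function(betaF, seF, betaM, seM) {
  if (any(seF <= 0) || any(seM <= 0)) stop("standard errors must be positive")
  q <- (betaF - betaM)^2 / (seF^2 + seM^2)
  list(q = q, p = .pFromChisq(q))
}

#' Heterogeneity Z-score
#'
#' `Z_het = (beta_f - beta_m) / sqrt(se_f^2 + se_m^2)`. The sign carries
#' which sex has the larger signed effect; `Z_het^2` equals Cochran's Q for
#' two strata.
#'
#' @inheritParams cochranQ
#' @return Numeric vector of Z-scores.
#' @export
zHet <- function(betaF, seF, betaM, seM) {
  if (any(seF <= 0) || any(seM <= 0)) stop("standard errors must be positive")
  (betaF - betaM) / sqrt(seF^2 + seM^2)
}

#' Convert a heterogeneity Z-score to the effect scale
#'
#' `beta_het = z / sqrt(2 p (1 - p) (n + z^2))` and
#' `se_het = 1 / sqrt(2 p (1 - p) (n + z^2))`, where `p` is the allele
#' frequency (the minor allele frequency of the harmonized pair is used
#' throughout the package) and `n` the total sample size. The ratio
#' `beta_het / se_het` reproduces `z` exactly.
#'
#' @param z Heterogeneity Z-score.
#' @param p Allele frequency, strictly inside (0,1).
#' @param n Total sample size (females + males), positive.
#' @return List with numeric vectors `beta` and `se`.
#' @export
zhetToEffect <- function(z, p, n) {
  if (any(p <= 0 | p >= 1)) stop("allele frequency must be strictly in (0,1)")
  if (any(n <= 0)) stop("sample size must be positive")
  denom <- sqrt(2 * p * (1 - p) * (n + z^2))
  list(beta = z / denom, se = 1 / denom)
}

#' Classify which sex drives a heterogeneous effect
#'
#' `female_driven` when the absolute female effect exceeds the absolute male
#' effect, else `male_driven`. Exact ties (measure zero on real data) are
#' assigned `male_driven` deterministically and counted in the log.
#'
#' @param betaF,betaM Signed effect estimates.
#' @return Character vector in `{"female_driven", "male_driven"}`.
#' @export
classifyDirection <- function(betaF, betaM) {
  ties <- abs(betaF) == abs(betaM)
  if (any(ties)) {
    .sexhetLog(sprintf("classifyDirection: %d exact |beta| ties assigned male_driven",
                       sum(ties)))
  }
  ifelse(abs(betaF) > abs(betaM), "female_driven", "male_driven")
}

#' Classify the mechanism of a sex-heterogeneous effect
#'
#' Using per-stratum nominal significance at level `alpha`:
#' `one_sex_only` when exactly one stratum is nominal, `opposite_direction`
#' when both are nominal with discordant signs, `magnitude_difference` when
#' both are nominal with concordant signs. SNPs nominal in neither stratum
#' return `NA`.
#'
#' @param pF,pM Per-stratum association p-values.
#' @param betaF,betaM Per-stratum signed effects.
#' @param alpha Per-sex nominal level (default 0.05).
#' @return Character vector.
#' @export
classifyMechanism <- function(pF, pM, betaF, betaM, alpha = 0.05) {
  sigF <- pF < alpha
  sigM <- pM < alpha
  out <- rep(NA_character_, length(pF))
  out[xor(sigF, sigM)] <- "one_sex_only"
  both <- sigF & sigM
  out[both & sign(betaF) != sign(betaM)] <- "opposite_direction"
  out[both & sign(betaF) == sign(betaM)] <- "magnitude_difference"
  out
}

#' Genomic inflation factor (lambda)
#'
#' `lambda = median(chi-square) / 0.4549364`, the chi-square(1) null median.
#' Supply either p-values (converted through the inverse upper tail; pass
#' `log.p = TRUE` with natural-log p-values to avoid underflow below
#' 1e-300) or chi-square statistics directly.
#'
#' @param p Upper-tail p-values (or their natural logs with `log.p = TRUE`).
#' @param chisq Chi-square(1 df) statistics; used if `p` is `NULL`.
#' @param log.p Interpret `p` as log p-values.
#' @return Scalar lambda.
#' @export
genomicInflation <- function(p = NULL, chisq = NULL, log.p = FALSE) {
  if (is.null(chisq)) {
    if (is.null(p) || !length(p)) stop("supply non-empty p or chisq")
    chisq <- .chisqFromP(p, log.p = log.p)
  }
  if (!length(chisq)) stop("empty input")
  median(chisq) / .CHISQ1_MEDIAN
}

#' Per-SNP sex-heterogeneity statistics for one trait
#'
#' Computes Cochran's Q, the heterogeneity Z-score, its conversion to the
#' effect scale, and the direction and mechanism classifications for every
#' SNP of a harmonized pair.
#'
#' @param paired A [PairedSumstats-class] object.
#' @param alpha Nominal level for [classifyMechanism()].
#' @return `data.frame` (one row per SNP) with columns `snp_id`, `chrom`,
#'   `pos`, `maf`, `n_total`, `beta_f`, `se_f`, `pvalue_f`, `beta_m`,
#'   `se_m`, `pvalue_m`, `q_stat`, `p_q`, `z_het`, `beta_het`, `se_het`,
#'   `direction`, `mechanism`.
#' @export
hetStats <- function(paired, alpha = 0.05) {
  stopifnot(is(paired, "PairedSumstats"))
  d <- paired@data
  cq <- cochranQ(d$beta_f, d$se_f, d$beta_m, d$se_m)
  z <- zHet(d$beta_f, d$se_f, d$beta_m, d$se_m)
  conv <- zhetToEffect(z, d$maf, d$n_total)
  data.frame(
    snp_id = d$snp_id, chrom = d$chrom, pos = d$pos,
    maf = d$maf, n_total = d$n_total,
    beta_f = d$beta_f, se_f = d$se_f, pvalue_f = d$pvalue_f,
    beta_m = d$beta_m, se_m = d$se_m, pvalue_m = d$pvalue_m,
    q_stat = cq$q, p_q = cq$p, z_het = z,
    beta_het = conv$beta, se_het = conv$se,
    direction = classifyDirection(d$beta_f, d$beta_m),
    mechanism = classifyMechanism(d$pvalue_f, d$pvalue_m, d$beta_f, d$beta_m,
                                  alpha = alpha),
    stringsAsFactors = FALSE)
}

#' Select trait-specific sex-het SNPs
#'
#' Retains SNPs with `p_q < pThreshold` and `maf >= mafMin` (the
#' genome-wide heterogeneity threshold 5e-8 and the 0.1 percent
#' minor-allele-frequency floor).
#'
#' @param het `data.frame` from [hetStats()].
#' @param pThreshold Cochran's Q p-value threshold.
#' @param mafMin Minimum minor allele frequency (inclusive).
#' @return Filtered `data.frame`.
#' @export
selectTraitSexHet <- function(het, pThreshold = 5e-8, mafMin = 0.001) {
  .stopifnotCols(het, c("p_q", "maf"), "het table")
  het[het$p_q < pThreshold & het$maf >= mafMin, , drop = FALSE]
}

#' Write per-trait heterogeneity records as TSV
#'
#' @param het `data.frame` from [hetStats()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeHetRecords <- function(het, path) {
  fwrite(het, path, sep = "\t")
  invisible(path)
}
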