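#' @include AllClasses.R
NULL

#' Sign the heterogeneity effect for cross-trait meta-analysis
#'
#' The meta-analysis input carries the magnitude of the converted
#' heterogeneity effect with a sign encoding which sex dominates: positive
#' when `|beta_f| > |beta_m|` (female-driven), negative otherwise.
#'
#' @param betaHet,seHet Converted heterogeneity effect and SE.
#' @param betaF,betaM Per-stratum signed marginal effects.
#' @return List with vectors `beta` (signed) and `se`.
#' @export
signedInput <- function(betaHet, seHet, betaF, betaM) {
  s <- ifelse(abs(betaF) > abs(betaM), 1, -1)
  list(beta = s * abs(betaHet), se = seHet)
}

#' Estimate between-trait correlation from null-band Z-scores
#'
#' Shared samples between two GWAS induce correlation between their null
#' Z-scores. For each trait pair the Pearson correlation of Z is computed
#' over SNPs where both traits fall in the null band `|z| < nullBand`;
#' pairs with fewer than `minSnps` such SNPs get correlation 0 with a
#' warning. This mirrors the overlap correction of cross-trait
#' meta-analysis software.
#'
#' @param zMatrix Numeric matrix, SNPs x traits, of per-trait Z-scores
#'   (NA where a SNP is missing in a trait).
#' @param nullBand Absolute-Z cutoff defining null SNPs (default 1).
#' @param minSnps Minimum null SNPs per pair (default 100).
#' @return Symmetric trait x trait correlation matrix with unit diagonal.
#' @export
estimateOverlapCorr <- function(zMatrix, nullBand = 1, minSnps = 100) {
  zMatrix <- as.matrix(zMatrix)
  t <- ncol(zMatrix)
  if (t < 2) stop("need at least two traits")
  cm <- diag(1, t)
  dimnames(cm) <- list(colnames(zMatrix), colnames(zMatrix))
  for (i in seq_len(t - 1)) {
    for (j in (i + 1):t) {
      sel <- !is.na(zMatrix[, i]) & !is.na(zMatrix[, j]) &
        abs(zMatrix[, i]) < nullBand & abs(zMatrix[, j]) < nullBand
      if (sum(sel) < minSnps) {
        warning(sprintf("overlap correlation (%d,%d): only %d null-band SNPs; using 0",
                        i, j, sum(sel)))
        r <- 0
      } else {
        r <- cor(zMatrix[sel, i], zMatrix[sel, j])
      }
      cm[i, j] <- cm[j, i] <- r
    }
  }
  cm
}

#' Fixed-effects meta-analysis of one SNP across traits
#'
#' Without `corr`, the standard inverse-variance fixed-effects estimate.
#' With `corr`, the correlated fixed-effects (Lin-Sullivan) estimate using
#' covariance `Sigma_ij = corr_ij * se_i * se_j`:
#' `beta = (1' Sigma^-1 b) / (1' Sigma^-1 1)`, `se = (1' Sigma^-1 1)^-1/2`.
#' Traits with missing data (`NA` beta or se) are dropped; a singular
#' covariance falls back to the uncorrected estimate with a warning.
#'
#' @param beta,se Per-trait effect estimates and SEs (NA = missing).
#' @param corr Optional trait x trait correlation matrix.
#' @return List with `beta`, `se`, `p` (two-sided normal) and `nTraits`.
#' @export
#' @examples
#' metaFixed(c(0.1, 0.1), c(0.1, 0.1))  # se = 0.0707
metaFixed <- function(beta, se, corr = NULL) {
  ok <- !is.na(beta) & !is.na(se)
  if (!any(ok)) stop("no trait with data for this SNP")
  beta <- beta[ok]; se <- se[ok]
  if (any(se <= 0)) stop("standard errors must be positive")
  if (is.null(corr) || length(beta) == 1) {
    w <- 1 / se^2
    b <- sum(w * beta) / sum(w)
    s <- 1 / sqrt(sum(w))
  } else {
    R <- corr[ok, ok, drop = FALSE]
    res <- tryCatch({
      Ri <- solve(R)
      u <- 1 / se
      denom <- drop(u %*% Ri %*% u)
      b <- drop(u %*% Ri %*% (beta / se)) / denom
      list(b = b, s = 1 / sqrt(denom))
    }, error = function(e) NULL)
    if (is.null(res) || !is.finite(res$s)) {
      warning("singular covariance; falling back to uncorrected meta-analysis")
      w <- 1 / se^2
      b <- sum(w * beta) / sum(w)
      s <- 1 / sqrt(sum(w))
    } else {
      b <- res$b; s <- res$s
    }
  }
  list(beta = b, se = s, p = .pTwoSidedZ(b / s), nTraits = length(beta))
}

#' Cross-trait meta-analysis table of heterogeneity effects
#'
#' Runs the (optionally correlated) fixed-effects meta-analysis of signed
#' heterogeneity effects for every SNP across a list of per-trait
#' heterogeneity tables, and attaches the leading trait (minimum per-trait
#' Cochran's Q p-value), its `best_p_q`, and the minor allele frequency of
#' the largest-sample contributing trait. SNPs missing in some traits are
#' meta-analyzed over the available traits.
#'
#' @param hetList Named list of [hetStats()] tables, one per trait.
#' @param corr Optional trait x trait correlation matrix (ordered and named
#'   like `hetList`) from [estimateOverlapCorr()].
#' @return `data.frame` with `snp_id`, `chrom`, `pos`, `maf`, `beta_meta`,
#'   `se_meta`, `p_meta`, `n_traits_contributing`, `leading_trait`,
#'   `best_p_q`.
#' @export
metaFixedTable <- function(hetList, corr = NULL) {
  stopifnot(is.list(hetList), length(hetList) >= 1)
  traits <- names(hetList)
  if (is.null(traits)) traits <- paste0("trait", seq_along(hetList))
  snps <- sort(unique(unlist(lapply(hetList, `[[`, "snp_id"))))
  nT <- length(hetList)
  B <- Z <- S <- P <- MAF <- Nt <- matrix(NA_real_, length(snps), nT)
  for (k in seq_len(nT)) {
    h <- hetList[[k]]
    idx <- match(h$snp_id, snps)
    si <- signedInput(h$beta_het, h$se_het, h$beta_f, h$beta_m)
    B[idx, k] <- si$beta
    S[idx, k] <- si$se
    P[idx, k] <- h$p_q
    MAF[idx, k] <- h$maf
    Nt[idx, k] <- h$n_total
  }
  avail <- !is.na(B) & !is.na(S)

  if (is.null(corr)) {
    W <- ifelse(avail, 1 / S^2, 0)
    sw <- rowSums(W)
    betaMeta <- rowSums(ifelse(avail, W * B, 0)) / sw
    seMeta <- 1 / sqrt(sw)
  } else {
    betaMeta <- seMeta <- rep(NA_real_, length(snps))
    pat <- apply(avail, 1, function(a) paste(which(a), collapse = ","))
    for (pp in unique(pat)) {
      ks <- as.integer(strsplit(pp, ",")[[1]])
      rows <- which(pat == pp)
      if (length(ks) == 1) {
        betaMeta[rows] <- B[rows, ks]
        seMeta[rows] <- S[rows, ks]
        next
      }
      Ri <- tryCatch(solve(corr[ks, ks, drop = FALSE]), error = function(e) NULL)
      if (is.null(Ri)) {
        warning("singular covariance for a trait pattern; using uncorrected weights")
        W <- 1 / S[rows, ks, drop = FALSE]^2
        sw <- rowSums(W)
        betaMeta[rows] <- rowSums(W * B[rows, ks, drop = FALSE]) / sw
        seMeta[rows] <- 1 / sqrt(sw)
      } else {
        U <- 1 / S[rows, ks, drop = FALSE]
        Zs <- B[rows, ks, drop = FALSE] / S[rows, ks, drop = FALSE]
        UM <- U %*% Ri
        denom <- rowSums(UM * U)
        betaMeta[rows] <- rowSums(UM * Zs) / denom
        seMeta[rows] <- 1 / sqrt(denom)
      }
    }
  }

  bestK <- apply(ifelse(is.na(P), Inf, P), 1, which.min)
  bestP <- P[cbind(seq_along(snps), bestK)]
  # MAF re-applied post-meta from the largest-sample contributing trait.
  nK <- apply(ifelse(is.na(Nt), -Inf, Nt), 1, which.max)
  maf <- MAF[cbind(seq_along(snps), nK)]

  chrom <- pos <- rep(NA, length(snps))
  for (k in seq_len(nT)) {
    h <- hetList[[k]]
    idx <- match(h$snp_id, snps)
    fill <- is.na(chrom[idx])
    chrom[idx[fill]] <- h$chrom[fill]
    pos[idx[fill]] <- h$pos[fill]
  }

  data.frame(
    snp_id = snps, chrom = as.character(chrom), pos = as.numeric(pos),
    maf = maf, beta_meta = betaMeta, se_meta = seMeta,
    p_meta = .pTwoSidedZ(betaMeta / seMeta),
    n_traits_contributing = rowSums(avail),
    leading_trait = traits[bestK], best_p_q = bestP,
    stringsAsFactors = FALSE)
}

#' Combine univariate and multivariate sex-het SNPs
#'
#' Takes the union of SNPs genome-wide significant in any single trait's
#' heterogeneity test and SNPs significant in the cross-trait meta-analysis
#' (both after the MAF floor), tags each with its provenance, and carries
#' the leading trait, best Cochran's Q p-value, direction and mechanism (of
#' the leading trait) forward as clumping input.
#'
#' @param hetList Named list of full per-trait [hetStats()] tables.
#' @param meta [metaFixedTable()] output.
#' @param pThreshold Significance threshold (default 5e-8).
#' @param mafMin Minor allele frequency floor (default 0.001).
#' @return `data.frame` of candidate SNPs with a `provenance` column in
#'   `{"univariate_only", "multivariate_only", "both"}`.
#' @export
combineUniMulti <- function(hetList, meta, pThreshold = 5e-8, mafMin = 0.001) {
  uniSnps <- unique(unlist(lapply(hetList, function(h) {
    selectTraitSexHet(h, pThreshold, mafMin)$snp_id
  })))
  multiSnps <- meta$snp_id[meta$p_meta < pThreshold & !is.na(meta$maf) &
                             meta$maf >= mafMin]
  all <- union(uniSnps, multiSnps)
  if (!length(all)) {
    return(data.frame(snp_id = character(0), chrom = character(0),
                      pos = numeric(0), maf = numeric(0),
                      best_p_q = numeric(0), leading_trait = character(0),
                      direction = character(0), mechanism = character(0),
                      provenance = character(0), stringsAsFactors = FALSE))
  }
  m <- meta[match(all, meta$snp_id), ]
  out <- data.frame(
    snp_id = all, chrom = m$chrom, pos = m$pos, maf = m$maf,
    best_p_q = m$best_p_q, leading_trait = m$leading_trait,
    stringsAsFactors = FALSE)
  # direction/mechanism taken from the leading trait's paired records
  out$direction <- NA_character_
  out$mechanism <- NA_character_
  for (tr in unique(out$leading_trait)) {
    h <- hetList[[tr]]
    if (is.null(h)) next
    rows <- which(out$leading_trait == tr)
    idx <- match(out$snp_id[rows], h$snp_id)
    out$direction[rows] <- h$direction[idx]
    out$mechanism[rows] <- h$mechanism[idx]
  }
  out$provenance <- ifelse(all %in% uniSnps & all %in% multiSnps, "both",
                           ifelse(all %in% uniSnps, "univariate_only",
                                  "multivariate_only"))
  rownames(out) <- NULL
  out
}

#' Write meta-analysis records as TSV
#' @param meta [metaFixedTable()] output.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeMetaRecords <- function(meta, path) {
  fwrite(meta, path, sep = "\t")
  invisible(path)
}
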