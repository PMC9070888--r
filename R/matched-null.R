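#' @include AllClasses.R AllGenerics.R
NULL

.mafTolerance <- function(maf, boundary = 0.01, tolLow = 0.001, tolHigh = 0.02) {
  # catalog maf exactly at the boundary uses the wider (common-variant) rule
  ifelse(maf < boundary, tolLow, tolHigh)
}

#' Build the matching index for permuted sex-homogeneous SNP sets
#'
#' Pool SNPs are ranked by their combined-sex marginal effect (the
#' inverse-variance meta-analysis of the female and male betas). A pool SNP
#' is eligible as a null match iff it is not itself in the sex-het catalog,
#' is not in LD (`r2 > 0.2`) with any catalog SNP, and (optionally) belongs
#' to `restrict`. For every catalog entry the index pre-computes the
#' eligible candidates within the allele-frequency tolerance (±0.001 for
#' MAF < 0.01, ±0.02 otherwise) and the ±`rankWindow` positions of the
#' ranked marginal-effect list.
#'
#' @param pool A [PairedSumstats-class] (or its `data.frame`) covering all
#'   candidate SNPs for the leading trait; must contain every catalog SNP.
#' @param catalog A [SexHetCatalog-class].
#' @param ld An [LDProvider-class]; LD neighbors of catalog SNPs at
#'   `r2 > ldExclude` are ineligible.
#' @param rankWindow Half-width of the marginal-effect rank window
#'   (default 75).
#' @param ldExclude LD exclusion threshold (default 0.2, exclusive).
#' @param restrict Optional character vector of SNP ids; eligibility is
#'   additionally intersected with this set (used for the conditional
#'   predicted-eQTL analysis).
#' @return A list of class `"MatchingIndex"`.
#' @export
buildMatchingIndex <- function(pool, catalog, ld, rankWindow = 75,
                               ldExclude = 0.2, restrict = NULL) {
  stopifnot(is(catalog, "SexHetCatalog"), is(ld, "LDProvider"))
  pd <- if (is(pool, "PairedSumstats")) pool@data else as.data.frame(pool)
  .stopifnotCols(pd, c("snp_id", "maf", "beta_f", "se_f", "beta_m", "se_m"),
                 "pool")
  cat_d <- catalog@data
  if (nrow(pd) < nrow(cat_d)) stop("pool smaller than catalog")
  missing <- setdiff(cat_d$snp_id, pd$snp_id)
  if (length(missing)) {
    stop(sprintf("pool must contain every catalog SNP (%d missing)",
                 length(missing)))
  }

  wf <- 1 / pd$se_f^2; wm <- 1 / pd$se_m^2
  marginal <- (wf * pd$beta_f + wm * pd$beta_m) / (wf + wm)
  # deterministic ranking of the pool by combined-sex marginal effect
  rank <- order(order(marginal, pd$snp_id))

  inCatalog <- pd$snp_id %in% cat_d$snp_id
  ldExcluded <- rep(FALSE, nrow(pd))
  nbr <- unique(unlist(lapply(cat_d$snp_id, function(s) {
    nb <- get0(s, envir = ld@neighbors, ifnotfound = NULL)
    if (is.null(nb)) character(0) else nb$other[nb$r2 > ldExclude]
  })))
  ldExcluded[pd$snp_id %in% nbr] <- TRUE
  eligible <- !inCatalog & !ldExcluded
  if (!is.null(restrict)) eligible <- eligible & pd$snp_id %in% restrict

  catIdx <- match(cat_d$snp_id, pd$snp_id)
  catRank <- rank[catIdx]
  catMaf <- cat_d$maf
  tol <- .mafTolerance(catMaf)

  ordRank <- order(rank)           # pool indices sorted by rank
  rankSorted <- rank[ordRank]
  candidates <- vector("list", nrow(cat_d))
  for (i in seq_len(nrow(cat_d))) {
    lo <- catRank[i] - rankWindow
    hi <- catRank[i] + rankWindow
    slice <- ordRank[max(1, lo):min(length(rankSorted), hi)]
    sel <- slice[eligible[slice] & abs(pd$maf[slice] - catMaf[i]) <= tol[i]]
    candidates[[i]] <- sel
  }

  structure(list(
    pool = data.frame(snp_id = pd$snp_id, maf = pd$maf, rank = rank,
                      eligible = eligible, stringsAsFactors = FALSE),
    catalog_snp = cat_d$snp_id, catalog_maf = catMaf, catalog_rank = catRank,
    maf_tol = tol, rank_window = rankWindow, candidates = candidates),
    class = "MatchingIndex")
}

#' @export
print.MatchingIndex <- function(x, ...) {
  cat(sprintf("MatchingIndex: %d catalog entries over a pool of %d SNPs (%d eligible)\n",
              length(x$catalog_snp), nrow(x$pool), sum(x$pool$eligible)))
  cat(sprintf("  median candidates per entry: %g\n",
              median(lengths(x$candidates))))
  invisible(x)
}

# Candidates for entry i under tolerances widened by `factor`.
.relaxedCandidates <- function(index, i, factor) {
  p <- index$pool
  tol <- index$maf_tol[i] * factor
  win <- index$rank_window * factor
  which(p$eligible &
          abs(p$maf - index$catalog_maf[i]) <= tol &
          abs(p$rank - index$catalog_rank[i]) <= win)
}

#' Sample one matched set of sex-homogeneous SNPs
#'
#' For each catalog entry, one SNP is drawn uniformly among the eligible
#' pool SNPs satisfying both matching tolerances, without replacement
#' within the set. Entries with no remaining candidate are relaxed by
#' doubling both tolerances up to three times, then by a nearest-neighbor
#' (allele-frequency) fallback; every relaxation is recorded in the set's
#' metadata and logged.
#'
#' @param index A `"MatchingIndex"` from [buildMatchingIndex()].
#' @param seed Integer seed of this set's RNG stream.
#' @return A [MatchedNullSet-class].
#' @export
sampleMatchedSet <- function(index, seed = 1L) {
  nEntry <- length(index$catalog_snp)
  p <- index$pool
  used <- logical(nrow(p))
  chosen <- integer(nEntry)
  relaxed <- integer(nEntry)
  .withSeed(seed, {
    for (i in seq_len(nEntry)) {
      cand <- index$candidates[[i]]
      cand <- cand[!used[cand]]
      lvl <- 0L
      while (!length(cand) && lvl < 3L) {
        lvl <- lvl + 1L
        cand <- .relaxedCandidates(index, i, 2^lvl)
        cand <- cand[!used[cand]]
      }
      if (!length(cand)) {
        # nearest unused eligible SNP by allele frequency
        lvl <- -1L
        pool_ok <- which(p$eligible & !used)
        if (!length(pool_ok)) stop("matching pool exhausted")
        cand <- pool_ok[which.min(abs(p$maf[pool_ok] - index$catalog_maf[i]))]
      }
      pick <- if (length(cand) == 1) cand else cand[sample.int(length(cand), 1)]
      chosen[i] <- pick
      used[pick] <- TRUE
      relaxed[i] <- lvl
    }
  })
  if (any(relaxed != 0)) {
    .sexhetLog(sprintf("sampleMatchedSet(seed=%d): %d entries needed relaxed tolerances",
                       seed, sum(relaxed != 0)))
  }
  meta <- data.frame(
    catalog_snp = index$catalog_snp,
    null_snp = p$snp_id[chosen],
    maf_delta = p$maf[chosen] - index$catalog_maf,
    rank_delta = p$rank[chosen] - index$catalog_rank,
    relaxed = relaxed, stringsAsFactors = FALSE)
  new("MatchedNullSet", snps = p$snp_id[chosen], meta = meta,
      seed = as.integer(seed))
}

#' Sample many matched null sets with reproducible per-set streams
#'
#' Per-set seeds are derived deterministically from the master seed, so
#' any set can be regenerated independently.
#'
#' @param index A `"MatchingIndex"`.
#' @param nSets Number of sets (the reference workflow uses 100 or 1,000).
#' @param seed Master seed.
#' @return List of [MatchedNullSet-class] objects.
#' @export
sampleMatchedSets <- function(index, nSets = 1000, seed = 1L) {
  seeds <- .deriveSeeds(seed, nSets)
  lapply(seeds, function(s) sampleMatchedSet(index, seed = s))
}

#' Empirical p-value of an observed statistic within a permutation null
#'
#' `empP = (1 + #\{null >= observed\}) / (N + 1)` for the upper tail
#' (`tail = "ge"`); mirrored for `tail = "le"`.
#'
#' @param observed Scalar observed statistic.
#' @param nullValues Statistics from `N` permuted sets.
#' @param tail `"ge"` (enrichment) or `"le"` (depletion).
#' @return Scalar empirical p-value in `(0, 1]`.
#' @export
empiricalP <- function(observed, nullValues, tail = c("ge", "le")) {
  tail <- match.arg(tail)
  stopifnot(length(nullValues) >= 1)
  k <- if (tail == "ge") sum(nullValues >= observed) else
    sum(nullValues <= observed)
  (1 + k) / (length(nullValues) + 1)
}

#' Matching diagnostics: MAF distributions of catalog, pool and null sets
#'
#' Reports the median minor allele frequency of the catalog, of the
#' eligible pool, and of each null set, along with Kolmogorov-Smirnov
#' distances to the catalog MAF distribution. A well-matched sampler
#' yields null-set KS distances far below the pool's.
#'
#' @param catalog A [SexHetCatalog-class].
#' @param nullSets List of [MatchedNullSet-class] objects.
#' @param pool Pool table (or [PairedSumstats-class]) with `snp_id`, `maf`.
#' @return List with `medians` (named numeric) and `ks` (`data.frame` of
#'   per-set and pool KS distances).
#' @export
matchingDiagnostics <- function(catalog, nullSets, pool) {
  stopifnot(length(nullSets) >= 1)
  pd <- if (is(pool, "PairedSumstats")) pool@data else as.data.frame(pool)
  catMaf <- catalog@data$maf
  poolMaf <- pd$maf
  setMaf <- lapply(nullSets, function(s) pd$maf[match(s@snps, pd$snp_id)])
  ksStat <- function(x) {
    suppressWarnings(unname(ks.test(x, catMaf)$statistic))
  }
  list(
    medians = c(catalog = median(catMaf), pool = median(poolMaf),
                null_sets = median(vapply(setMaf, median, numeric(1)))),
    ks = data.frame(
      what = c("pool", paste0("set", seq_along(setMaf))),
      ks_distance = c(ksStat(poolMaf),
                      vapply(setMaf, ksStat, numeric(1)))))
}

#' Write matched null sets and a manifest
#'
#' One SNP-list file per set plus a `manifest.tsv` recording the per-set
#' seed and relaxation count.
#'
#' @param nullSets List of [MatchedNullSet-class] objects.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeNullSets <- function(nullSets, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  man <- data.frame(set = seq_along(nullSets),
                    file = sprintf("set%04d.txt", seq_along(nullSets)),
                    seed = vapply(nullSets, function(s) s@seed, integer(1)),
                    n_relaxed = vapply(nullSets, function(s)
                      sum(s@meta$relaxed != 0), integer(1)))
  for (i in seq_along(nullSets)) {
    writeLines(nullSets[[i]]@snps, file.path(dir, man$file[i]))
  }
  fwrite(man, file.path(dir, "manifest.tsv"), sep = "\t")
  invisible(dir)
}
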