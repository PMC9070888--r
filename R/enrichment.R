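#' @include AllClasses.R AllGenerics.R matched-null.R
NULL

.diseaseP <- function(disease) {
  d <- if (is(disease, "Sumstats")) disease@data else as.data.frame(disease)
  .stopifnotCols(d, c("snp_id", "pvalue"), "disease table")
  setNames(d$pvalue, d$snp_id)
}

.pctBelowAlpha <- function(snps, pMap, alpha) {
  p <- pMap[match(snps, names(pMap))]
  p <- p[!is.na(p)]
  if (!length(p)) return(c(n = 0, pct = NA_real_, k = 0))
  k <- sum(p < alpha)
  c(n = length(p), pct = 100 * k / length(p), k = k)
}

#' Enrichment of catalog SNPs in disease/trait association signal
#'
#' Among the SNPs shared between the catalog and a disease summary-stat
#' table, computes the percentage with association `p < alpha` and tests it
#' against the null expectation of `100 * alpha` percent with a 1-df
#' chi-square goodness-of-fit test on counts (exact binomial available via
#' `test = "exact"`). When matched null sets are supplied, the same
#' percentage is computed for every null set and an upper-tail empirical
#' p-value is attached.
#'
#' @param catalog A [SexHetCatalog-class] (or character vector of SNP ids).
#' @param disease A [Sumstats-class] (or `data.frame` with `snp_id`,
#'   `pvalue`) of combined-sex disease/trait associations.
#' @param alpha Association significance level (default 0.05).
#' @param nullSets Optional list of [MatchedNullSet-class] objects (or
#'   character vectors of SNP ids).
#' @param test `"chisq"` (default) or `"exact"`.
#' @return An [EnrichmentResult-class].
#' @export
signalEnrichment <- function(catalog, disease, alpha = 0.05, nullSets = NULL,
                             test = c("chisq", "exact")) {
  test <- match.arg(test)
  snps <- if (is(catalog, "SexHetCatalog")) catalog@data$snp_id else
    as.character(catalog)
  pMap <- .diseaseP(disease)
  obs <- .pctBelowAlpha(snps, pMap, alpha)
  if (obs["n"] == 0) {
    stop("no overlap between the catalog and the disease table")
  }
  n <- unname(obs["n"]); k <- unname(obs["k"])
  expCount <- alpha * n
  chi2P <- if (test == "chisq") {
    suppressWarnings(chisq.test(c(k, n - k), p = c(alpha, 1 - alpha))$p.value)
  } else {
    binom.test(k, n, p = alpha)$p.value
  }
  nullStats <- numeric(0)
  empP <- NA_real_
  if (!is.null(nullSets) && length(nullSets)) {
    nullStats <- vapply(nullSets, function(s) {
      ids <- if (is(s, "MatchedNullSet")) s@snps else as.character(s)
      unname(.pctBelowAlpha(ids, pMap, alpha)["pct"])
    }, numeric(1))
    empP <- empiricalP(unname(obs["pct"]), nullStats, tail = "ge")
  }
  .EnrichmentResult(nOverlap = n, observedStat = unname(obs["pct"]),
                    expectedStat = 100 * alpha, expectedCount = unname(expCount),
                    chi2P = chi2P, empP = empP, nullStats = nullStats,
                    items = list(n_significant = unname(k), alpha = alpha))
}

#' Compare female- and male-driven subset enrichment for one disease
#'
#' Runs [signalEnrichment()] on the female-driven and male-driven catalog
#' subsets and compares their hit rates with a 2x2 chi-square test; the
#' subset ratio (female percent / male percent) summarizes the sex
#' specificity of the enrichment.
#'
#' @inheritParams signalEnrichment
#' @return List with per-subset [EnrichmentResult-class] objects, the
#'   `ratio` (female/male observed percent) and `chi2_p` of the 2x2 test.
#' @export
sexSubsetEnrichment <- function(catalog, disease, alpha = 0.05) {
  stopifnot(is(catalog, "SexHetCatalog"))
  d <- catalog@data
  .stopifnotCols(d, "direction", "catalog")
  fem <- signalEnrichment(d$snp_id[d$direction == "female_driven"], disease,
                          alpha = alpha)
  mal <- signalEnrichment(d$snp_id[d$direction == "male_driven"], disease,
                          alpha = alpha)
  kf <- fem@items$n_significant; nf <- fem@nOverlap
  km <- mal@items$n_significant; nm <- mal@nOverlap
  chi2 <- suppressWarnings(
    chisq.test(matrix(c(kf, nf - kf, km, nm - km), nrow = 2))$p.value)
  list(female = fem, male = mal,
       ratio = fem@observedStat / mal@observedStat, chi2_p = chi2)
}

#' Overlap between catalog SNPs and a target SNP set
#'
#' Computes the percent of catalog SNPs belonging to a target SNP set
#' (e.g. meQTLs at p < 1e-14, or predicted-eQTL SNPs), optionally counting
#' the unique items (CpG probes, eGenes) attached to the overlapping SNPs
#' through a SNP-to-item multimap. With matched null sets, upper-tail
#' empirical p-values are attached both for the overlap percentage and for
#' the unique item count.
#'
#' @param catalog A [SexHetCatalog-class] or character vector of SNP ids.
#' @param targetSnps Character vector of target SNP ids (pre-filtered by
#'   the caller, e.g. meQTLs at p < 1e-14).
#' @param perSnpItems Optional `data.frame` multimap with columns `snp` and
#'   `item` (a SNP may map to several items).
#' @param nullSets Optional list of [MatchedNullSet-class] objects.
#' @return An [EnrichmentResult-class]; `items` carries `n_items`,
#'   `items_per_snp_range` and `emp_p_items` when a multimap is supplied.
#' @export
snpsetOverlap <- function(catalog, targetSnps, perSnpItems = NULL,
                          nullSets = NULL) {
  snps <- if (is(catalog, "SexHetCatalog")) catalog@data$snp_id else
    as.character(catalog)
  targetSnps <- unique(as.character(targetSnps))
  ov <- intersect(snps, targetSnps)
  pct <- 100 * length(ov) / length(snps)
  items <- list()
  if (!is.null(perSnpItems)) {
    .stopifnotCols(perSnpItems, c("snp", "item"), "perSnpItems")
    hit <- perSnpItems[perSnpItems$snp %in% ov, , drop = FALSE]
    perSnp <- table(unique(hit)[["snp"]])
    items$n_items <- length(unique(hit$item))
    items$items_per_snp_range <- if (length(perSnp)) range(as.integer(perSnp))
      else c(0L, 0L)
  }
  nullStats <- numeric(0)
  empP <- NA_real_
  if (!is.null(nullSets) && length(nullSets)) {
    nullPct <- vapply(nullSets, function(s) {
      ids <- if (is(s, "MatchedNullSet")) s@snps else as.character(s)
      100 * length(intersect(ids, targetSnps)) / length(ids)
    }, numeric(1))
    nullStats <- nullPct
    empP <- empiricalP(pct, nullPct, tail = "ge")
    if (!is.null(perSnpItems)) {
      nullItems <- vapply(nullSets, function(s) {
        ids <- if (is(s, "MatchedNullSet")) s@snps else as.character(s)
        hv <- perSnpItems$item[perSnpItems$snp %in% intersect(ids, targetSnps)]
        length(unique(hv))
      }, numeric(1))
      items$null_n_items <- nullItems
      items$emp_p_items <- empiricalP(items$n_items, nullItems, tail = "ge")
    }
  }
  .EnrichmentResult(nOverlap = length(ov), observedStat = pct,
                    expectedStat = if (length(nullStats)) median(nullStats)
                      else NA_real_,
                    empP = empP, nullStats = nullStats, items = items)
}

#' Overlap between catalog SNPs and named interval annotations
#'
#' For each named annotation, computes the percent of catalog SNPs whose
#' 1-based position falls inside at least one interval, with empirical
#' p-values in both directions (enrichment and depletion) against matched
#' null sets.
#'
#' @param catalog A [SexHetCatalog-class] (positions taken from its table).
#' @param annotations Named list of `GRanges` (or a `GRangesList`).
#' @param nullSets Optional list of [MatchedNullSet-class] objects.
#' @param pool Pool table with `snp_id`, `chrom`, `pos`, required to place
#'   null-set SNPs when `nullSets` is given.
#' @return `data.frame` with one row per annotation: `annotation`,
#'   `n_inside`, `pct`, `emp_p_enrich`, `emp_p_deplete`.
#' @export
intervalOverlap <- function(catalog, annotations, nullSets = NULL,
                            pool = NULL) {
  stopifnot(is(catalog, "SexHetCatalog"))
  d <- catalog@data
  annotations <- as.list(annotations)
  if (is.null(names(annotations))) {
    names(annotations) <- paste0("annotation", seq_along(annotations))
  }
  annChrom <- unique(unlist(lapply(annotations, function(g)
    as.character(seqnames(g)))))
  unmatched <- setdiff(unique(d$chrom), annChrom)
  if (length(unmatched) == length(unique(d$chrom))) {
    stop("chromosome names of the catalog do not match the annotations: ",
         paste(unmatched, collapse = ", "))
  }
  catGr <- GRanges(d$chrom, IRanges(d$pos, d$pos))
  pctInside <- function(gr, ann) {
    100 * sum(!is.na(findOverlaps(gr, ann, select = "first"))) / length(gr)
  }
  nullGr <- NULL
  if (!is.null(nullSets) && length(nullSets)) {
    if (is.null(pool)) stop("pool positions required to score null sets")
    pd <- if (is(pool, "PairedSumstats")) pool@data else as.data.frame(pool)
    .stopifnotCols(pd, c("snp_id", "chrom", "pos"), "pool")
    nullGr <- lapply(nullSets, function(s) {
      ids <- if (is(s, "MatchedNullSet")) s@snps else as.character(s)
      idx <- match(ids, pd$snp_id)
      GRanges(pd$chrom[idx], IRanges(pd$pos[idx], pd$pos[idx]))
    })
  }
  rows <- lapply(names(annotations), function(nm) {
    ann <- annotations[[nm]]
    pct <- pctInside(catGr, ann)
    pe <- pd_ <- NA_real_
    if (!is.null(nullGr)) {
      nullPct <- vapply(nullGr, pctInside, numeric(1), ann = ann)
      pe <- empiricalP(pct, nullPct, tail = "ge")
      pd_ <- empiricalP(pct, nullPct, tail = "le")
    }
    data.frame(annotation = nm,
               n_inside = round(pct * nrow(d) / 100),
               pct = pct, emp_p_enrich = pe, emp_p_deplete = pd_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Filter a predicted-eQTL map by tissue
#'
#' @param preqtl `data.frame` with columns `snp`, `egene`, `tissue`.
#' @param tissues Keep only these tissues (NULL = all).
#' @param excludeTissues Drop these tissues (applied after `tissues`).
#' @return Filtered `data.frame`.
#' @export
filterPreqtlTissues <- function(preqtl, tissues = NULL, excludeTissues = NULL) {
  .stopifnotCols(preqtl, c("snp", "egene", "tissue"), "preqtl map")
  if (!is.null(tissues)) preqtl <- preqtl[preqtl$tissue %in% tissues, ]
  if (!is.null(excludeTissues)) {
    preqtl <- preqtl[!preqtl$tissue %in% excludeTissues, ]
  }
  preqtl
}

#' Conditional disease enrichment within predicted-eQTL SNPs
#'
#' Tests whether the sex-het disease/trait enrichment persists among SNPs
#' that predict gene expression: [signalEnrichment()] is recomputed on the
#' catalog subset that belongs to the predicted-eQTL (Pr-eQTL) map, against
#' matched null sets drawn only from sex-homogeneous Pr-eQTL SNPs (the
#' matching index is rebuilt with eligibility restricted to Pr-eQTL
#' membership).
#'
#' @param catalog A [SexHetCatalog-class].
#' @param preqtl Pr-eQTL map (`snp`, `egene`, `tissue`), optionally
#'   pre-filtered with [filterPreqtlTissues()].
#' @param diseases Named list of disease tables ([Sumstats-class] or
#'   `data.frame`).
#' @param pool,ld Pool and LD provider for [buildMatchingIndex()].
#' @param nSets Number of null sets (default 1000).
#' @param seed Master seed for null sampling.
#' @param alpha Association significance level.
#' @return Named list of [EnrichmentResult-class], one per disease.
#' @export
conditionalPreqtlEnrichment <- function(catalog, preqtl, diseases, pool, ld,
                                        nSets = 1000, seed = 1L, alpha = 0.05) {
  stopifnot(is(catalog, "SexHetCatalog"))
  preqtlSnps <- unique(preqtl$snp)
  subIds <- intersect(catalog@data$snp_id, preqtlSnps)
  if (!length(subIds)) stop("no catalog SNPs in the Pr-eQTL map")
  sub <- SexHetCatalog(catalog@data[catalog@data$snp_id %in% subIds, ],
                       r2Threshold = catalog@r2Threshold)
  pd <- if (is(pool, "PairedSumstats")) pool@data else as.data.frame(pool)
  nEligible <- sum(pd$snp_id %in% preqtlSnps & !pd$snp_id %in% catalog@data$snp_id)
  if (nEligible < length(subIds)) {
    stop(sprintf("too few eligible sex-homogeneous Pr-eQTL SNPs (%d) for a catalog subset of %d",
                 nEligible, length(subIds)))
  }
  idx <- buildMatchingIndex(pool, sub, ld, restrict = preqtlSnps)
  nulls <- sampleMatchedSets(idx, nSets = nSets, seed = seed)
  out <- lapply(diseases, function(dz) {
    signalEnrichment(sub, dz, alpha = alpha, nullSets = nulls)
  })
  names(out) <- names(diseases)
  out
}
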