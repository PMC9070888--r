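#' @include AllClasses.R matched-null.R
NULL

# Core ORA arithmetic on counts; p from Fisher's exact test on the 2x2
# list-membership x set-membership table.
.oraFromCounts <- function(nRef, nObs, listSize, universeSize,
                           alternative = "two.sided") {
  expected <- nRef * listSize / universeSize
  fe <- if (expected > 0) nObs / expected else NA_real_
  tab <- matrix(c(nObs, listSize - nObs,
                  nRef - nObs, universeSize - listSize - nRef + nObs),
                nrow = 2)
  p <- fisher.test(tab, alternative = alternative)$p.value
  list(expected = expected, fe = fe,
       direction = if (nObs > expected) "+" else "-", p = p)
}

#' Overrepresentation analysis of a gene list against gene sets
#'
#' For each gene set, computes the expected member count
#' `n_reference * list_size / universe_size`, the fold enrichment
#' `FE = n_observed / n_expected`, the direction, a Fisher's exact p-value
#' on the 2x2 membership table (two-sided by default, the convention of
#' common ORA servers; one-tailed via `alternative`), and
#' Benjamini-Hochberg FDR across sets. Genes absent from the universe are
#' removed from both the list and the sets before testing.
#'
#' @param geneList Character vector of genes (e.g. from [assignedGenes()]).
#' @param geneSets Named list of character vectors (from [readGmt()]).
#' @param universe Character vector of background genes. Defaults to the
#'   union of the gene sets.
#' @param alternative Passed to [stats::fisher.test()].
#' @return `data.frame` with one row per set: `set_name`, `n_reference`,
#'   `n_observed`, `n_expected`, `fold_enrichment`, `direction`,
#'   `p_value`, `fdr`.
#' @export
oraTest <- function(geneList, geneSets, universe = NULL,
                    alternative = "two.sided") {
  if (!length(geneList)) stop("empty gene list")
  if (is.null(universe)) universe <- unique(unlist(geneSets))
  universe <- unique(universe)
  listU <- unique(intersect(geneList, universe))
  if (!length(listU)) stop("no gene of the list is in the universe")
  dropped <- length(unique(geneList)) - length(listU)
  if (dropped > 0) {
    .sexhetLog(sprintf("oraTest: %d list genes absent from the universe excluded",
                       dropped))
  }
  rows <- lapply(names(geneSets), function(nm) {
    set <- intersect(unique(geneSets[[nm]]), universe)
    res <- .oraFromCounts(length(set), length(intersect(listU, set)),
                          length(listU), length(universe), alternative)
    data.frame(set_name = nm, n_reference = length(set),
               n_observed = length(intersect(listU, set)),
               n_expected = res$expected, fold_enrichment = res$fe,
               direction = res$direction, p_value = res$p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fdr <- fdrBH(out$p_value)
  rownames(out) <- NULL
  out
}

#' Benjamini-Hochberg false discovery rate
#'
#' Step-up BH adjustment with monotonicity enforcement.
#'
#' @param p Vector of p-values in (0,1].
#' @return Vector of FDR-adjusted values.
#' @export
fdrBH <- function(p) {
  p.adjust(p, method = "BH")
}

#' Permutation-calibrated empirical p-values for ORA results
#'
#' Recomputes the fold enrichment of every gene set for each permuted gene
#' list (derived from matched sex-homogeneous SNP sets via the same
#' annotation rule as the observed list) and converts the rank of the
#' observed fold enrichment into an empirical p-value: upper tail for
#' overrepresented sets (`direction == "+"`), lower tail for
#' underrepresented sets.
#'
#' @param observed `data.frame` from [oraTest()] on the observed gene list.
#' @param permLists List of permuted gene lists (character vectors).
#' @param geneSets,universe As in [oraTest()] (same universe as observed).
#' @return `observed` with an `emp_p` column appended.
#' @export
oraEmpirical <- function(observed, permLists, geneSets, universe = NULL) {
  stopifnot(length(permLists) >= 1)
  if (is.null(universe)) universe <- unique(unlist(geneSets))
  universe <- unique(universe)
  setsU <- lapply(geneSets[observed$set_name], function(s)
    intersect(unique(s), universe))
  permFE <- vapply(permLists, function(gl) {
    gl <- unique(intersect(gl, universe))
    ls <- length(gl)
    vapply(setsU, function(set) {
      expd <- length(set) * ls / length(universe)
      if (expd > 0) length(intersect(gl, set)) / expd else NA_real_
    }, numeric(1))
  }, numeric(nrow(observed)))
  permFE <- matrix(permFE, nrow = nrow(observed))
  observed$emp_p <- vapply(seq_len(nrow(observed)), function(i) {
    tail <- if (observed$direction[i] == "+") "ge" else "le"
    empiricalP(observed$fold_enrichment[i], permFE[i, ], tail = tail)
  }, numeric(1))
  observed
}
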