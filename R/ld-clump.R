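#' @include AllClasses.R AllGenerics.R
NULL

# Build the neighbor-list environment from a symmetric pair table.
# Entries are list(other = <chr>, r2 = <num>) keyed by SNP id.
.ldEnvFromPairs <- function(pairs) {
  env <- new.env(parent = emptyenv(), hash = TRUE)
  if (!nrow(pairs)) return(env)
  a <- c(pairs$snp_a, pairs$snp_b)
  b <- c(pairs$snp_b, pairs$snp_a)
  r2 <- c(pairs$r2, pairs$r2)
  keep <- a != b
  a <- a[keep]; b <- b[keep]; r2 <- r2[keep]
  sp <- split(seq_along(a), a)
  for (snp in names(sp)) {
    idx <- sp[[snp]]
    dup <- duplicated(b[idx])
    assign(snp, list(other = b[idx][!dup], r2 = r2[idx][!dup]), envir = env)
  }
  env
}

#' Build an LDProvider from a pair list
#'
#' @param pairs `data.frame` with columns `snp_a`, `snp_b`, `r2`. The list
#'   is symmetrized; self pairs are ignored (`r2(a,a)` is always 1).
#' @return An [LDProvider-class].
#' @export
ldFromPairs <- function(pairs) {
  .stopifnotCols(pairs, c("snp_a", "snp_b", "r2"), "LD pair list")
  if (nrow(pairs) && any(pairs$r2 < 0 | pairs$r2 > 1)) {
    stop("r2 must be in [0,1]")
  }
  new("LDProvider", neighbors = .ldEnvFromPairs(as.data.frame(pairs)))
}

#' Build a block-diagonal LDProvider
#'
#' All SNP pairs within a block share a common r-squared (exchangeable LD);
#' pairs across blocks have r-squared 0. This is the LD structure produced
#' by the synthetic-data generator.
#'
#' @param blocks Named vector (names = SNP ids) of block labels.
#' @param r2Within Within-block r-squared (default 0.5).
#' @return An [LDProvider-class].
#' @export
ldFromBlocks <- function(blocks, r2Within = 0.5) {
  stopifnot(!is.null(names(blocks)), r2Within >= 0, r2Within <= 1)
  env <- new.env(parent = emptyenv(), hash = TRUE)
  if (r2Within > 0) {
    for (members in split(names(blocks), as.character(blocks))) {
      k <- length(members)
      if (k < 2) next
      r2 <- rep(r2Within, k - 1)
      for (i in seq_len(k)) {
        assign(members[i], list(other = members[-i], r2 = r2), envir = env)
      }
    }
  }
  new("LDProvider", neighbors = env)
}

#' Read an LD pair list from TSV
#'
#' @param path Tab-delimited file with header columns `snp_a`, `snp_b`, `r2`.
#' @return An [LDProvider-class].
#' @export
readLdPairs <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  ldFromPairs(fread(path, sep = "\t", header = TRUE, data.table = FALSE,
                    showProgress = FALSE))
}

#' Write an LDProvider as a pair-list TSV
#' @param ld An [LDProvider-class].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeLdPairs <- function(ld, path) {
  keys <- ls(ld@neighbors)
  rows <- lapply(keys, function(snp) {
    d <- get(snp, envir = ld@neighbors)
    keep <- snp < d$other  # emit each unordered pair once
    if (!any(keep)) return(NULL)
    data.frame(snp_a = snp, other = d$other[keep], r2 = d$r2[keep],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(snp_a = character(0), snp_b = character(0),
                      r2 = numeric(0))
  } else {
    names(out) <- c("snp_a", "snp_b", "r2")
  }
  fwrite(out, path, sep = "\t")
  invisible(path)
}

#' @describeIn ldR2 pairwise lookup on the neighbor store
#' @export
setMethod("ldR2", "LDProvider", function(x, a, b) {
  n <- max(length(a), length(b))
  a <- rep_len(as.character(a), n)
  b <- rep_len(as.character(b), n)
  out <- numeric(n)
  for (i in seq_len(n)) {
    if (a[i] == b[i]) { out[i] <- 1; next }
    d <- mget(a[i], envir = x@neighbors, ifnotfound = list(NULL))[[1]]
    if (!is.null(d)) {
      hit <- match(b[i], d$other)
      if (!is.na(hit)) out[i] <- d$r2[hit]
    }
  }
  out
})

#' @describeIn ldNeighbors neighbors above a threshold
#' @export
setMethod("ldNeighbors", "LDProvider", function(x, snp, r2Min = 0.2) {
  d <- mget(as.character(snp), envir = x@neighbors,
            ifnotfound = list(NULL))[[1]]
  if (is.null(d)) return(character(0))
  d$other[d$r2 >= r2Min]
})

#' Greedy LD clumping of candidate sex-het SNPs
#'
#' Iterates candidates by ascending `best_p_q` (ties broken by chromosome,
#' position, then SNP id for determinism) and keeps a SNP iff its
#' r-squared with every already-kept SNP is below `r2Threshold`. SNPs
#' unknown to the LD provider are treated as independent and kept, with a
#' logged count. Clumping is genome-wide; the provider defines
#' cross-chromosome r-squared as 0.
#'
#' @param candidates `data.frame` with at least `snp_id`, `chrom`, `pos`,
#'   `maf`, `best_p_q` (extra columns are carried through), e.g. from
#'   [combineUniMulti()].
#' @param ld An [LDProvider-class].
#' @param r2Threshold Clumping threshold (default 0.2, exclusive).
#' @return A [SexHetCatalog-class] of independent tag SNPs.
#' @export
clumpSnps <- function(candidates, ld, r2Threshold = 0.2) {
  .stopifnotCols(candidates, c("snp_id", "chrom", "pos", "maf", "best_p_q"),
                 "candidates")
  if (!nrow(candidates)) stop("no candidate SNPs to clump")
  ord <- order(candidates$best_p_q, candidates$chrom, candidates$pos,
               candidates$snp_id)
  cand <- candidates[ord, , drop = FALSE]
  known <- vapply(cand$snp_id, function(s) {
    exists(s, envir = ld@neighbors, inherits = FALSE)
  }, logical(1))
  if (any(!known)) {
    .sexhetLog(sprintf("clumpSnps: %d candidate SNPs absent from the LD reference (kept as independent)",
                       sum(!known)))
  }
  kept <- new.env(parent = emptyenv(), hash = TRUE)
  keepRow <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    snp <- cand$snp_id[i]
    nb <- ldNeighbors(ld, snp, r2Min = r2Threshold)
    # reject only on neighbors strictly above/equal threshold already kept;
    # threshold itself excludes (catalog requires r2 < threshold)
    conflict <- any(vapply(nb, function(o) {
      exists(o, envir = kept, inherits = FALSE)
    }, logical(1)))
    if (!conflict) {
      keepRow[i] <- TRUE
      assign(snp, TRUE, envir = kept)
    }
  }
  SexHetCatalog(cand[keepRow, , drop = FALSE], r2Threshold = r2Threshold)
}

#' Write a SexHetCatalog as TSV
#' @param catalog A [SexHetCatalog-class].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeCatalog <- function(catalog, path) {
  fwrite(catalog@data, path, sep = "\t")
  invisible(path)
}
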