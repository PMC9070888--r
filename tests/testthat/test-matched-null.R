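# Build a pool PairedSumstats-like data.frame with controlled maf/beta.
makePool <- function(n, maf = NULL, beta = NULL, seed = 1) {
  withr::with_seed(seed, {
    if (is.null(maf)) maf <- runif(n, 0.05, 0.5)
    if (is.null(beta)) beta <- rnorm(n, 0, 0.1)
    data.frame(snp_id = sprintf("p%05d", seq_len(n)), chrom = "chr1",
               pos = seq_len(n) * 1000, maf = maf,
               beta_f = beta, se_f = 0.05, beta_m = beta, se_m = 0.05,
               stringsAsFactors = FALSE)
  })
}

emptyLd <- function() {
  ldFromPairs(data.frame(snp_a = character(0), snp_b = character(0),
                         r2 = numeric(0)))
}

catalogFromPool <- function(pool, idx) {
  SexHetCatalog(data.frame(snp_id = pool$snp_id[idx], chrom = "chr1",
                           pos = pool$pos[idx], maf = pool$maf[idx],
                           best_p_q = seq_along(idx) * 1e-9))
}

test_that("matching index excludes catalog SNPs and their LD neighbors", {
  pool <- makePool(500)
  cat <- catalogFromPool(pool, 1:5)
  ld <- ldFromPairs(data.frame(snp_a = pool$snp_id[1],
                               snp_b = pool$snp_id[c(10, 11)],
                               r2 = c(0.3, 0.15)))
  idx <- buildMatchingIndex(pool, cat, ld)
  elig <- setNames(idx$pool$eligible, idx$pool$snp_id)
  expect_false(any(elig[pool$snp_id[1:5]]))       # catalog SNPs ineligible
  expect_false(elig[pool$snp_id[10]])             # r2 = 0.3 > 0.2 excluded
  expect_true(elig[pool$snp_id[11]])              # r2 = 0.15 stays eligible
  # ranks agree with an independent sort oracle on the marginal effect
  marginal <- (pool$beta_f / 0.05^2 + pool$beta_m / 0.05^2) /
    (2 / 0.05^2)
  expect_equal(idx$pool$rank, rank(marginal, ties.method = "first"))
  expect_setequal(idx$pool$rank, seq_len(nrow(pool)))
  expect_error(buildMatchingIndex(pool[1:3, ], cat, ld), "smaller than catalog")
  expect_error(buildMatchingIndex(pool[-1, ], cat, ld), "every catalog SNP")
})

test_that("a shifted clone pool is matched within tolerance for every entry", {
  pool <- makePool(200)
  # clone each catalog SNP with a tiny maf perturbation and adjacent beta
  cat_idx <- 1:20
  clones <- pool[cat_idx, ]
  clones$snp_id <- paste0("c", clones$snp_id)
  clones$maf <- clones$maf + 5e-4
  clones$beta_f <- clones$beta_m <- clones$beta_f + 1e-6
  poolAll <- rbind(pool, clones)
  cat <- catalogFromPool(poolAll, cat_idx)
  idx <- buildMatchingIndex(poolAll, cat, emptyLd())
  set <- sampleMatchedSet(idx, seed = 3)
  m <- tbl(set)
  tol <- ifelse(cat@data$maf < 0.01, 0.001, 0.02)
  expect_true(all(abs(m$maf_delta) <= tol))
  expect_true(all(abs(m$rank_delta) <= 75))
  expect_true(all(m$relaxed == 0))
  expect_false(any(set@snps %in% snpIds(cat)))
  expect_equal(anyDuplicated(set@snps), 0)
})

test_that("sampling is seed-reproducible and varies across seeds", {
  pool <- makePool(2000)
  cat <- catalogFromPool(pool, seq(1, 400, by = 4))
  idx <- buildMatchingIndex(pool, cat, emptyLd())
  s1 <- sampleMatchedSet(idx, seed = 7)
  s2 <- sampleMatchedSet(idx, seed = 7)
  s3 <- sampleMatchedSet(idx, seed = 8)
  expect_identical(s1@snps, s2@snps)
  expect_false(identical(s1@snps, s3@snps))
  sets <- sampleMatchedSets(idx, nSets = 4, seed = 99)
  setsAgain <- sampleMatchedSets(idx, nSets = 4, seed = 99)
  expect_identical(lapply(sets, snpIds), lapply(setsAgain, snpIds))
})

test_that("the MAF boundary rule applies the wider tolerance at maf = 0.01", {
  pool <- makePool(400, maf = runif(400, 0.005, 0.03))
  pool$maf[1] <- 0.01
  cat <- catalogFromPool(pool, 1)
  idx <- buildMatchingIndex(pool, cat, emptyLd())
  expect_equal(idx$maf_tol, 0.02)
  pool$maf[1] <- 0.0099
  idx2 <- buildMatchingIndex(pool, catalogFromPool(pool, 1), emptyLd())
  expect_equal(idx2$maf_tol, 0.001)
})

test_that("entries with no in-tolerance candidate are relaxed and flagged", {
  # catalog SNP with a unique extreme maf: nothing within +/-0.02
  pool <- makePool(300, maf = c(0.45, runif(299, 0.05, 0.2)))
  cat <- catalogFromPool(pool, 1)
  idx <- buildMatchingIndex(pool, cat, emptyLd())
  expect_equal(lengths(idx$candidates), 0L)
  set <- sampleMatchedSet(idx, seed = 1)
  expect_true(all(set@meta$relaxed != 0))
})

test_that("empirical p follows the add-one rank formula and calibrates", {
  expect_equal(empiricalP(10, rep(1, 1000)), 1 / 1001)
  expect_equal(empiricalP(10, rep(1, 1000)), 0.000999, tolerance = 1e-3)
  nulls <- seq_len(999)
  expect_equal(empiricalP(500, nulls), 0.5, tolerance = 3e-3)
  expect_equal(empiricalP(0, nulls, tail = "le"), 1 / 1000)
  # calibration: empP of a null draw is Uniform on its support
  set.seed(10)
  emp <- replicate(500, {
    x <- rnorm(40)
    empiricalP(x[1], x[-1])
  })
  expect_gt(suppressWarnings(ks.test(emp, "punif")$p.value), 0.01)
  # enrichment/depletion tails double-count ties
  x <- rnorm(99)
  expect_gte(empiricalP(x[1], x[-1], "ge") + empiricalP(x[1], x[-1], "le"),
             1 + 1 / 99)
})

test_that("matched sets reproduce the catalog MAF distribution", {
  pool <- makePool(3000)
  cat <- catalogFromPool(pool, which(pool$maf > 0.3)[1:50])
  idx <- buildMatchingIndex(pool, cat, emptyLd())
  sets <- sampleMatchedSets(idx, nSets = 10, seed = 2)
  diag <- matchingDiagnostics(cat, sets, pool)
  expect_equal(unname(diag$medians["null_sets"]),
               unname(diag$medians["catalog"]), tolerance = 0.03)
  # brute-force median recomputation
  m1 <- median(pool$maf[match(sets[[1]]@snps, pool$snp_id)])
  expect_equal(diag$ks$ks_distance[1],
               unname(suppressWarnings(
                 ks.test(pool$maf, cat@data$maf)$statistic)))
  # matched sets are closer to the catalog than unmatched random sets
  set.seed(3)
  randomSet <- sample(pool$snp_id, 50)
  ksRandom <- suppressWarnings(ks.test(
    pool$maf[match(randomSet, pool$snp_id)], cat@data$maf)$statistic)
  ksMatched <- mean(diag$ks$ks_distance[-1])
  expect_lt(ksMatched, ksRandom)
})

test_that("null sets and manifest are written to disk", {
  pool <- makePool(500)
  cat <- catalogFromPool(pool, 1:10)
  idx <- buildMatchingIndex(pool, cat, emptyLd())
  sets <- sampleMatchedSets(idx, nSets = 3, seed = 5)
  dir <- withr::local_tempdir()
  writeNullSets(sets, dir)
  expect_true(file.exists(file.path(dir, "manifest.tsv")))
  expect_equal(readLines(file.path(dir, "set0001.txt")), sets[[1]]@snps)
})
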