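diseaseTable <- function(ids, p) {
  data.frame(snp_id = ids, pvalue = p, stringsAsFactors = FALSE)
}

simpleCatalog <- function(ids, chrom = "chr1", pos = NULL, maf = 0.2,
                          direction = NULL) {
  d <- data.frame(snp_id = ids, chrom = chrom,
                  pos = if (is.null(pos)) seq_along(ids) * 100 else pos,
                  maf = maf, best_p_q = seq_along(ids) * 1e-9,
                  stringsAsFactors = FALSE)
  if (!is.null(direction)) d$direction <- direction
  SexHetCatalog(d)
}

test_that("signal enrichment recomputes percent, expected count and chi2", {
  ids <- sprintf("r%04d", 1:1405)
  p <- c(runif(107, 0, 0.049), runif(1298, 0.05, 1))
  er <- signalEnrichment(simpleCatalog(ids), diseaseTable(ids, p))
  expect_equal(er@nOverlap, 1405L)
  expect_equal(er@observedStat, 100 * 107 / 1405)
  expect_equal(er@expectedCount, 0.05 * 1405)
  expect_equal(er@chi2P,
               chisq.test(c(107, 1298), p = c(0.05, 0.95))$p.value)
  # all overlap p-values at 0.5: zero percent observed, 5% expected
  er0 <- signalEnrichment(simpleCatalog(ids), diseaseTable(ids, rep(0.5, 1405)))
  expect_equal(er0@observedStat, 0)
  expect_equal(er0@expectedStat, 5)
  # exact binomial option
  erx <- signalEnrichment(simpleCatalog(ids[1:50]),
                          diseaseTable(ids, p), test = "exact")
  k <- sum(p[1:50] < 0.05)
  expect_equal(erx@chi2P, binom.test(k, 50, 0.05)$p.value)
})

test_that("overlap is restricted to shared SNPs and zero overlap errors", {
  cat <- simpleCatalog(c("a", "b", "c"))
  dz <- diseaseTable(c("b", "c", "x"), c(0.01, 0.6, 0.001))
  er <- signalEnrichment(cat, dz)
  expect_equal(er@nOverlap, 2L)
  expect_equal(er@observedStat, 50)
  expect_error(signalEnrichment(cat, diseaseTable("zzz", 0.5)), "no overlap")
})

test_that("observed percent equals a brute-force count on synthetic stats", {
  sc <- smallScenario()
  dz <- simulateDisease(sc$cfg, sc$sim$truth, scenario = "pleiotropic")
  ids <- sc$sim$truth$snp_id[seq(1, 2000, by = 7)]
  er <- signalEnrichment(simpleCatalog(ids), dz)
  pv <- tbl(dz)$pvalue[match(ids, snpIds(dz))]
  expect_equal(er@observedStat, 100 * mean(pv < 0.05))
  expect_equal(er@expectedCount, 0.05 * length(ids))
})

test_that("empirical p uses matched null sets on the same statistic", {
  ids <- sprintf("r%03d", 1:100)
  p <- setNames(runif(100), ids)
  p[1:20] <- 0.001      # catalog SNPs carry strong signal
  cat <- simpleCatalog(ids[1:20])
  nulls <- lapply(1:19, function(i) ids[20 + (1:20) + (i %% 4)])
  er <- signalEnrichment(cat, diseaseTable(ids, unname(p)), nullSets = nulls)
  expect_equal(er@empP, 1 / 20)
  expect_equal(length(er@nullStats), 19)
})

test_that("sex-subset comparison reports the 2x2 chi-square and ratio", {
  ids <- sprintf("r%03d", 1:200)
  dir <- rep(c("female_driven", "male_driven"), each = 100)
  p <- c(runif(100, 0, 0.04), runif(100, 0.5, 1))  # only female subset enriched
  res <- sexSubsetEnrichment(simpleCatalog(ids, direction = dir),
                             diseaseTable(ids, p))
  expect_equal(res$female@observedStat, 100)
  expect_equal(res$male@observedStat, 0)
  expect_lt(res$chi2_p, 1e-6)
})

test_that("SNP-set overlap counts unique items and per-SNP ranges", {
  cat <- simpleCatalog(sprintf("r%02d", 1:20))
  target <- c(sprintf("r%02d", 1:5), "x1", "x2")
  map <- data.frame(snp = c("r01", "r01", "r02", "x1"),
                    item = c("cg1", "cg2", "cg1", "cg9"))
  er <- snpsetOverlap(cat, target, perSnpItems = map)
  expect_equal(er@nOverlap, 5L)
  expect_equal(er@observedStat, 25)
  expect_equal(er@items$n_items, 2)                  # cg1, cg2
  expect_equal(er@items$items_per_snp_range, c(1L, 2L))
  expect_equal(snpsetOverlap(cat, character(0))@observedStat, 0)
  # brute-force proportions on a synthetic map
  sc <- smallScenario(nSnps = 1000)
  ann <- simulateAnnotations(sc$cfg, sc$sim$truth)
  ids <- sc$sim$truth$snp_id[1:400]
  er2 <- snpsetOverlap(simpleCatalog(ids), unique(ann$preqtl$snp))
  expect_equal(er2@observedStat,
               100 * mean(ids %in% ann$preqtl$snp))
})

test_that("interval overlap follows BED coordinates with both-tail empP", {
  gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(11, 20))
  cat <- simpleCatalog(c("a", "b", "c"), pos = c(15, 10, 21))
  res <- intervalOverlap(cat, list(win = gr))
  expect_equal(res$pct, 100 / 3)
  # annotation covering everything yields 100%
  whole <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 1e6))
  expect_equal(intervalOverlap(cat, list(all = whole))$pct, 100)
  expect_error(
    intervalOverlap(simpleCatalog("z", chrom = "chrZ"), list(win = gr)),
    "chrZ")
  # empirical p in both tails against null sets drawn from a pool
  pool <- data.frame(snp_id = sprintf("p%03d", 1:300), chrom = "chr1",
                     pos = sample(1:1000, 300))
  nulls <- lapply(1:9, function(i) sample(pool$snp_id, 3))
  res2 <- intervalOverlap(cat, list(win = gr), nullSets = nulls, pool = pool)
  expect_gte(res2$emp_p_enrich + res2$emp_p_deplete, 1 + 1 / 10)
})

test_that("interval overlap equals a brute-force scan on synthetic SNPs", {
  sc <- smallScenario(nSnps = 1000)
  ann <- simulateAnnotations(sc$cfg, sc$sim$truth)
  tr <- sc$sim$truth
  cat <- SexHetCatalog(data.frame(snp_id = tr$snp_id, chrom = tr$chrom,
                                  pos = tr$pos, maf = tr$maf,
                                  best_p_q = seq_len(nrow(tr)) * 1e-9))
  res <- intervalOverlap(cat, ann$intervals[1])
  g <- ann$intervals[[1]]
  inside <- vapply(seq_len(nrow(tr)), function(i) {
    any(as.character(GenomicRanges::seqnames(g)) == tr$chrom[i] &
          GenomicRanges::start(g) <= tr$pos[i] &
          GenomicRanges::end(g) >= tr$pos[i])
  }, logical(1))
  expect_equal(res$pct, 100 * mean(inside))
})

test_that("tissue filtering subsets the Pr-eQTL map", {
  map <- data.frame(snp = c("a", "b", "c"), egene = c("g1", "g2", "g3"),
                    tissue = c("brain_1", "tissue_2", "brain_3"))
  expect_equal(filterPreqtlTissues(map, tissues = c("brain_1", "brain_3"))$snp,
               c("a", "c"))
  expect_equal(filterPreqtlTissues(
    map, excludeTissues = paste0("brain_", 1:13))$snp, "b")
})

test_that("conditional Pr-eQTL enrichment separates mediation scenarios", {
  sc <- smallScenario(nSnps = 6000, seed = 21)
  ann <- simulateAnnotations(sc$cfg, sc$sim$truth)
  hetList <- lapply(sc$paired, hetStats)
  meta <- metaFixedTable(hetList)
  cand <- combineUniMulti(hetList, meta)
  catalog <- clumpSnps(cand, ann$ld)
  preqtlSnps <- unique(ann$preqtl$snp)

  # expression-mediated disease with no sex-het excess: signal sits on all
  # Pr-eQTL SNPs alike, so the conditional test should be non-significant
  dzMediated <- simulateDisease(sc$cfg, sc$sim$truth, scenario = "carriers",
                                carrierSnps = preqtlSnps, seed = 31)
  resNull <- conditionalPreqtlEnrichment(
    catalog, ann$preqtl, list(dz = dzMediated), sc$paired[[1]], ann$ld,
    nSets = 49, seed = 41)
  expect_gt(resNull$dz@empP, 0.05)

  # extra disease signal specific to sex-het Pr-eQTLs: significant
  hetPr <- intersect(snpIds(catalog), preqtlSnps)
  dzExcess <- simulateDisease(sc$cfg, sc$sim$truth, scenario = "carriers",
                              carrierSnps = hetPr, seed = 32)
  resSig <- conditionalPreqtlEnrichment(
    catalog, ann$preqtl, list(dz = dzExcess), sc$paired[[1]], ann$ld,
    nSets = 49, seed = 42)
  expect_lt(resSig$dz@empP, 0.05)

  # empty sex-het Pr-eQTL subset errors
  emptyMap <- data.frame(snp = "nonexistent", egene = "g", tissue = "t")
  expect_error(conditionalPreqtlEnrichment(
    catalog, emptyMap, list(dz = dzMediated), sc$paired[[1]], ann$ld),
    "no catalog SNPs")
})
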