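test_that("reading a well-formed file preserves all rows and values", {
  path <- withr::local_tempfile(fileext = ".tsv")
  d <- makeSumstatsDf(5)
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  ss <- readSumstats(path)
  expect_equal(length(ss), 5)
  expect_equal(tbl(ss)$beta, d$beta)
  expect_equal(snpIds(ss), d$snp_id)
})

test_that("rows violating invariants are dropped and counted", {
  d <- makeSumstatsDf(6)
  d$eaf[2] <- 1.3
  d$se[4] <- -1
  ss <- Sumstats(d)
  expect_equal(length(ss), 4)
  expect_equal(ss@nDropped, 2L)
  expect_false(any(c("rs002", "rs004") %in% snpIds(ss)))
})

test_that("a missing mandatory column is a hard error", {
  path <- withr::local_tempfile(fileext = ".tsv")
  d <- makeSumstatsDf(3)
  d$se <- NULL
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(readSumstats(path), "se")
})

test_that("write/read round trip is the identity on generator output", {
  cfg <- simConfig(nSnps = 200, nTraits = 1, seed = 42)
  sim <- simulateSumstats(cfg)
  x <- sim$sumstats$trait1$female
  path <- withr::local_tempfile(fileext = ".tsv.gz")
  writeSumstats(x, path)
  y <- readSumstats(path, trait = x@trait, stratum = x@stratum)
  expect_equal(tbl(y), tbl(x), tolerance = 1e-12)
})

test_that("dialect presets map consortium-style headers", {
  path <- withr::local_tempfile(fileext = ".tsv")
  d <- makeSumstatsDf(4)
  names(d) <- unname(sumstatsDialect("giant"))
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  ss <- readSumstats(path, dialect = sumstatsDialect("giant"))
  expect_equal(length(ss), 4)
  expect_named(tbl(ss), names(sumstatsDialect("default")))
})

test_that("harmonizePair aligns orientation, flips swapped male alleles", {
  f <- makeSumstats(3, stratum = "female")
  # same orientation: untouched
  m <- makeSumstats(3, stratum = "male", beta = c(0.2, 0.2, 0.2))
  p <- harmonizePair(f, m)
  expect_equal(tbl(p)$beta_m, rep(0.2, 3))
  # swapped alleles: beta negated, eaf complemented
  ms <- makeSumstats(3, stratum = "male", effect_allele = "G",
                     other_allele = "A", beta = 0.2, eaf = 0.3)
  ps <- harmonizePair(f, ms)
  expect_equal(tbl(ps)$beta_m, rep(-0.2, 3))
  expect_equal(tbl(ps)$eaf_m, rep(0.7, 3))
  # maf and n_total populated from the female stratum / both strata
  expect_equal(tbl(p)$maf, pmin(tbl(p)$eaf_f, 1 - tbl(p)$eaf_f))
  expect_equal(tbl(p)$n_total, tbl(p)$n_f + tbl(p)$n_m)
})

test_that("strand-ambiguous and mismatched SNPs are dropped with counts", {
  f <- makeSumstats(6)
  d <- makeSumstatsDf(6)
  d$effect_allele[1] <- "A"; d$other_allele[1] <- "T"   # ambiguous
  d$effect_allele[2] <- "C"; d$other_allele[2] <- "G"   # ambiguous
  d$effect_allele[3] <- "C"; d$other_allele[3] <- "T"   # mismatch vs A/G
  m <- Sumstats(d, stratum = "male")
  p <- harmonizePair(f, m)
  expect_equal(length(p), 3)
  expect_equal(unname(p@nDropped["ambiguous"]), 2L)
  expect_equal(unname(p@nDropped["mismatched"]), 1L)
})

test_that("ambiguous-SNP drops match the planted count from the generator", {
  cfg <- simConfig(nSnps = 500, nTraits = 1, ambiguousFrac = 0.1, seed = 9)
  sim <- simulateSumstats(cfg)
  p <- harmonizePair(sim$sumstats$trait1$female, sim$sumstats$trait1$male)
  d <- tbl(sim$sumstats$trait1$female)
  nPlanted <- sum((d$effect_allele == "A" & d$other_allele == "T") |
                    (d$effect_allele == "T" & d$other_allele == "A") |
                    (d$effect_allele == "C" & d$other_allele == "G") |
                    (d$effect_allele == "G" & d$other_allele == "C"))
  expect_equal(unname(p@nDropped["ambiguous"]), nPlanted)
  expect_equal(length(p), 500 - nPlanted)
})

test_that("harmonization is invariant to input orientation shuffling", {
  f <- makeSumstats(50, eaf = runif(50, 0.05, 0.95), beta = rnorm(50, 0, 0.1))
  md <- makeSumstatsDf(50, eaf = runif(50, 0.05, 0.95),
                       beta = rnorm(50, 0, 0.1))
  mShuffled <- md
  flip <- seq_len(50) %% 2 == 0
  mShuffled$effect_allele[flip] <- md$other_allele[flip]
  mShuffled$other_allele[flip] <- md$effect_allele[flip]
  mShuffled$beta[flip] <- -md$beta[flip]
  mShuffled$eaf[flip] <- 1 - md$eaf[flip]
  p1 <- harmonizePair(f, Sumstats(md, stratum = "male"))
  p2 <- harmonizePair(f, Sumstats(mShuffled, stratum = "male"))
  expect_equal(tbl(p1), tbl(p2), tolerance = 1e-12)
})

test_that("GMT round trips and BED follows the 0-based half-open convention", {
  gmt <- withr::local_tempfile(fileext = ".gmt")
  sets <- list(alpha = c("G1", "G2", "G3"), beta = c("G4", "G5", "G6"))
  writeGmt(sets, gmt)
  expect_equal(readGmt(gmt), sets)

  bed <- withr::local_tempfile(fileext = ".bed")
  writeLines("chr1\t10\t20", bed)
  gr <- readBed(bed)
  hit <- function(pos) {
    length(GenomicRanges::findOverlaps(
      GenomicRanges::GRanges("chr1", IRanges::IRanges(pos, pos)), gr)) > 0
  }
  expect_true(hit(15))
  expect_true(hit(11))
  expect_false(hit(10))
  expect_false(hit(21))
})

test_that("pLI and QTL map readers validate and drop malformed rows", {
  pli <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene\tpli", "GENE1\t0.99", "GENE2\t0.01", "GENE3\tnope"), pli)
  expect_warning(v <- readPli(pli), "malformed")
  expect_equal(unname(v["GENE1"]), 0.99)
  expect_equal(length(v), 2)

  qtl <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("snp\tcpg\tp\ttissue",
               "rs1\tcg1\t1e-20\tcord_blood",
               "rs2\t\t1e-20\tcord_blood",
               "rs3\tcg3\t2\tcord_blood"), qtl)
  expect_warning(m <- readQtlMap(qtl, "meqtl"), "malformed")
  expect_equal(m$snp, "rs1")
})
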