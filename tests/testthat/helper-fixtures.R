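options(sexhet.verbose = FALSE)

# Minimal well-formed summary-statistics data.frame; override any column.
makeSumstatsDf <- function(n = 5, ...) {
  d <- data.frame(
    snp_id = sprintf("rs%03d", seq_len(n)),
    chrom = "chr1",
    pos = seq_len(n) * 1000,
    effect_allele = "A",
    other_allele = "G",
    eaf = seq(0.1, 0.4, length.out = n),
    beta = rep(0.1, n),
    se = rep(0.05, n),
    pvalue = rep(0.5, n),
    n = rep(10000, n),
    stringsAsFactors = FALSE)
  over <- list(...)
  for (nm in names(over)) d[[nm]] <- over[[nm]]
  d
}

makeSumstats <- function(n = 5, trait = "t", stratum = "female", ...) {
  Sumstats(makeSumstatsDf(n, ...), trait = trait, stratum = stratum)
}

# A harmonized pair with configurable per-stratum effects.
makePaired <- function(n = 5, betaF = 0.1, betaM = 0.1, seF = 0.05,
                       seM = 0.05, maf = NULL, ...) {
  f <- makeSumstats(n, stratum = "female", beta = rep_len(betaF, n),
                    se = rep_len(seF, n), ...)
  m <- makeSumstats(n, stratum = "male", beta = rep_len(betaM, n),
                    se = rep_len(seM, n), ...)
  harmonizePair(f, m)
}

# Tiny simulated scenario shared by several tests.
smallScenario <- function(nSnps = 4000, seed = 11, ...) {
  cfg <- simConfig(nSnps = nSnps, nTraits = 2, sexhetFrac = 0.005,
                   seed = seed, ...)
  sim <- simulateSumstats(cfg)
  list(cfg = cfg, sim = sim,
       paired = lapply(sim$sumstats, function(tr)
         harmonizePair(tr$female, tr$male)))
}
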