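#' @include AllClasses.R sumstats-io.R ld-clump.R
NULL

#' Configuration for the synthetic-data generator
#'
#' Returns a validated configuration list with the default study
#' conditions: a three-trait, 100,000-SNP genome with GIANT/UK-Biobank
#' scale per-stratum sample sizes, exchangeable LD blocks of 20 SNPs,
#' planted sex-heterogeneous SNPs (one per LD block) at standardized effect
#' differences 4, 5 and 6, a mechanism mix mirroring the observed
#' proportions of one-sex-only, opposite-direction and magnitude
#' heterogeneity, and annotation densities on the scale of the reference
#' maps (17 percent predicted-eQTL membership with a 1.28-fold sex-het
#' excess, 5 percent meQTL membership).
#'
#' @param ... Named overrides of any default listed below.
#' @return List of class `"SimConfig"`.
#' @export
#' @examples
#' cfg <- simConfig(nSnps = 2000, nTraits = 2, seed = 7)
simConfig <- function(...) {
  cfg <- list(
    nSnps = 100000L,
    nTraits = 3L,
    nFemale = 170000,          # per-trait female stratum size
    nMale = 150000,            # per-trait male stratum size
    nChrom = 4L,
    snpSpacing = 1500,         # bp between adjacent SNPs
    mafBeta = c(0.8, 3),       # Beta shape parameters of the MAF spectrum
    ldBlockSize = 20L,
    ldR2Within = 0.5,          # exchangeable within-block LD r-squared
    sexhetFrac = 0.003,        # fraction of SNPs with planted sex-het effects
    dzGrid = c(4, 5, 6),       # planted |delta beta| / SE(delta) grid
    mechanismMix = c(one_sex_only = 0.668, opposite_direction = 0.326,
                     magnitude_difference = 0.006),
    assocFrac = 0.01,          # fraction of SNPs with sex-shared trait effects
    assocZ = 5,                # SD of the marginal association Z among them
    ambiguousFrac = 0,         # fraction of strand-ambiguous (A/T, C/G) SNPs
    diseasePleioFrac = 0.1,    # sex-het SNPs carrying disease signal
    diseaseZ = 3,              # mean |Z| of planted disease associations
    meqtlFrac = 0.05,
    meqtlSexhetExcess = 1.16,
    preqtlFrac = 0.17,
    preqtlSexhetExcess = 1.28,
    preqtlBrainShare = 0.56,   # chance a Pr-eQTL SNP hits a brain tissue
    nRegulatory = 50L,
    regulatoryCoverage = 0.1,
    geneLength = 20000,
    geneGap = 30000,
    exonsPerGene = 3L,
    pliHighFrac = 0.2,
    nGeneSets = 6L,
    geneSetBaseline = 0.05,    # baseline gene-set membership probability
    geneSetSexhetExcess = 3,   # fold excess for sex-het-specific sets
    seed = 1L)
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("unknown SimConfig field(s): ", paste(bad, collapse = ", "))
  cfg <- modifyList(cfg, over)
  stopifnot(cfg$nSnps >= 1, cfg$nTraits >= 1, cfg$ldBlockSize >= 1,
            cfg$ldR2Within >= 0, cfg$ldR2Within <= 1,
            cfg$sexhetFrac >= 0, cfg$sexhetFrac <= 1,
            abs(sum(cfg$mechanismMix) - 1) < 1e-8)
  structure(cfg, class = "SimConfig")
}

# Shared genome layout: positions, blocks, maf, alleles. Deterministic
# given the RNG state of the caller.
.simGenome <- function(cfg) {
  n <- cfg$nSnps
  perChrom <- ceiling(n / cfg$nChrom)
  chromIdx <- ((seq_len(n) - 1) %/% perChrom) + 1
  within <- (seq_len(n) - 1) %% perChrom
  chrom <- paste0("chr", chromIdx)
  pos <- 10000 + within * cfg$snpSpacing
  block <- paste0("b", chromIdx, "_", within %/% cfg$ldBlockSize)
  maf <- 0.001 + 0.499 * rbeta(n, cfg$mafBeta[1], cfg$mafBeta[2])
  flip <- runif(n) < 0.5
  eaf <- ifelse(flip, 1 - maf, maf)
  pairs <- matrix(c("A", "C", "A", "G", "T", "C", "T", "G"), ncol = 2,
                  byrow = TRUE)
  pick <- sample.int(4, n, replace = TRUE)
  ea <- pairs[pick, 1]; oa <- pairs[pick, 2]
  if (cfg$ambiguousFrac > 0) {
    amb <- runif(n) < cfg$ambiguousFrac
    ambPair <- matrix(c("A", "T", "C", "G"), ncol = 2, byrow = TRUE)
    pickA <- sample.int(2, sum(amb), replace = TRUE)
    ea[amb] <- ambPair[pickA, 1]; oa[amb] <- ambPair[pickA, 2]
  }
  data.frame(snp_id = sprintf("rs%07d", seq_len(n)), chrom = chrom, pos = pos,
             block = block, maf = maf, eaf = eaf, effect_allele = ea,
             other_allele = oa, stringsAsFactors = FALSE)
}

#' Simulate sex-stratified summary statistics with planted sex-het effects
#'
#' Generates per-trait female and male [Sumstats-class] tables plus a truth
#' table. Standard errors follow `se = 1 / sqrt(2 maf (1 - maf) n)` per
#' stratum; observed effects are the true effects plus correlated Gaussian
#' noise (exchangeable within LD blocks, noise correlation equal to the
#' square root of the block r-squared). Planted sex-het SNPs (at most one
#' per LD block) receive an effect difference of `dz` standard errors of
#' the difference, realized by the mechanism class drawn from
#' `mechanismMix`, identically in every trait; a separate set of SNPs
#' carries sex-shared trait associations.
#'
#' @param cfg A `"SimConfig"` from [simConfig()].
#' @return List with `sumstats` (per trait, a list with `female` and
#'   `male` [Sumstats-class]), and `truth` (`data.frame` with `snp_id`,
#'   `chrom`, `pos`, `block`, `maf`, `is_sexhet`, `dz`, `mechanism`,
#'   `sexhet_sex`, `is_assoc`).
#' @export
simulateSumstats <- function(cfg) {
  stopifnot(inherits(cfg, "SimConfig"))
  .withSeed(cfg$seed, {
    g <- .simGenome(cfg)
    n <- cfg$nSnps
    seF <- 1 / sqrt(2 * g$maf * (1 - g$maf) * cfg$nFemale)
    seM <- 1 / sqrt(2 * g$maf * (1 - g$maf) * cfg$nMale)
    seDiff <- sqrt(seF^2 + seM^2)

    # planted sex-het SNPs: at most one per LD block so that clumping keeps
    # each planted signal as its own tag
    nHet <- round(cfg$sexhetFrac * n)
    hetIdx <- integer(0)
    if (nHet > 0) {
      byBlock <- split(seq_len(n), g$block)
      blocks <- sample(names(byBlock), min(nHet, length(byBlock)))
      hetIdx <- vapply(byBlock[blocks], function(ix)
        ix[sample.int(length(ix), 1)], integer(1))
      hetIdx <- unname(hetIdx)
    }
    dz <- rep(0, n)
    dz[hetIdx] <- .resample(rep_len(cfg$dzGrid, length(hetIdx)))
    mech <- rep(NA_character_, n)
    mech[hetIdx] <- sample(names(cfg$mechanismMix), length(hetIdx),
                           replace = TRUE, prob = cfg$mechanismMix)
    hetSex <- rep(NA_character_, n)
    hetSex[hetIdx] <- sample(c("F", "M"), length(hetIdx), replace = TRUE)
    hetSign <- sample(c(-1, 1), n, replace = TRUE)

    # sex-shared marginal associations, excluding planted sex-het SNPs
    isAssoc <- rep(FALSE, n)
    nAssoc <- round(cfg$assocFrac * n)
    if (nAssoc > 0) {
      poolIdx <- setdiff(seq_len(n), hetIdx)
      isAssoc[sample(poolIdx, min(nAssoc, length(poolIdx)))] <- TRUE
    }
    seComb <- 1 / sqrt(2 * g$maf * (1 - g$maf) * (cfg$nFemale + cfg$nMale))

    # true sex-specific effects, shared across traits
    delta <- dz * seDiff * hetSign
    betaTrueF <- betaTrueM <- rep(0, n)
    oneSex <- which(mech == "one_sex_only")
    opp <- which(mech == "opposite_direction")
    mag <- which(mech == "magnitude_difference")
    fDriven <- hetSex == "F"
    betaTrueF[oneSex] <- ifelse(fDriven[oneSex], delta[oneSex], 0)
    betaTrueM[oneSex] <- ifelse(fDriven[oneSex], 0, -delta[oneSex])
    betaTrueF[opp] <- ifelse(fDriven[opp], 0.75, 0.25) * delta[opp]
    betaTrueM[opp] <- betaTrueF[opp] - delta[opp]
    betaTrueF[mag] <- ifelse(fDriven[mag], 1.5, 0.5) * delta[mag]
    betaTrueM[mag] <- betaTrueF[mag] - delta[mag]

    blockId <- match(g$block, unique(g$block))
    rho <- sqrt(cfg$ldR2Within)  # noise correlation = LD r
    noise <- function() {
      shared <- rnorm(max(blockId))[blockId]
      sqrt(rho) * shared + sqrt(1 - rho) * rnorm(n)
    }
    mkSumstats <- function(beta, se, nStratum, trait, stratum) {
      p <- .pTwoSidedZ(beta / se)
      p[p == 0] <- .Machine$double.xmin
      Sumstats(data.frame(
        snp_id = g$snp_id, chrom = g$chrom, pos = g$pos,
        effect_allele = g$effect_allele, other_allele = g$other_allele,
        eaf = g$eaf, beta = beta, se = se, pvalue = p, n = nStratum,
        stringsAsFactors = FALSE), trait = trait, stratum = stratum)
    }

    sumstats <- vector("list", cfg$nTraits)
    names(sumstats) <- paste0("trait", seq_len(cfg$nTraits))
    for (t in seq_len(cfg$nTraits)) {
      b0 <- rep(0, n)
      if (any(isAssoc)) {
        b0[isAssoc] <- rnorm(sum(isAssoc), 0, cfg$assocZ) * seComb[isAssoc]
      }
      obsF <- b0 + betaTrueF + seF * noise()
      obsM <- b0 + betaTrueM + seM * noise()
      sumstats[[t]] <- list(
        female = mkSumstats(obsF, seF, cfg$nFemale, names(sumstats)[t], "female"),
        male = mkSumstats(obsM, seM, cfg$nMale, names(sumstats)[t], "male"))
    }
    truth <- data.frame(
      snp_id = g$snp_id, chrom = g$chrom, pos = g$pos, block = g$block,
      maf = g$maf, is_sexhet = seq_len(n) %in% hetIdx, dz = dz,
      mechanism = mech, sexhet_sex = hetSex, is_assoc = isAssoc,
      stringsAsFactors = FALSE)
    list(sumstats = sumstats, truth = truth)
  })
}

#' Simulate combined-sex disease summary statistics
#'
#' Null SNPs receive standard-normal Z-scores, hence Uniform(0,1) p-values.
#' Under the `"pleiotropic"` scenario a configured fraction of the planted
#' sex-het SNPs carries disease signal (mean absolute Z `diseaseZ`); under
#' `"carriers"` the signal is planted exactly on `carrierSnps` (used for
#' expression-mediated scenarios); `"null"` plants nothing.
#'
#' @param cfg A `"SimConfig"`.
#' @param truth Truth table from [simulateSumstats()].
#' @param scenario `"pleiotropic"`, `"null"` or `"carriers"`.
#' @param carrierSnps SNP ids carrying signal under `"carriers"`.
#' @param seed Seed for this table (default derived from `cfg$seed`).
#' @param trait Label for the resulting table.
#' @return A combined-sex [Sumstats-class].
#' @export
simulateDisease <- function(cfg, truth,
                            scenario = c("pleiotropic", "null", "carriers"),
                            carrierSnps = NULL, seed = cfg$seed + 10000L,
                            trait = "disease") {
  scenario <- match.arg(scenario)
  stopifnot(inherits(cfg, "SimConfig"))
  .withSeed(seed, {
    n <- nrow(truth)
    z <- rnorm(n)
    carriers <- switch(scenario,
      null = integer(0),
      pleiotropic = {
        het <- which(truth$is_sexhet)
        .resample(het, round(cfg$diseasePleioFrac * length(het)))
      },
      carriers = which(truth$snp_id %in% carrierSnps))
    if (length(carriers)) {
      z[carriers] <- (cfg$diseaseZ + rnorm(length(carriers))) *
        sample(c(-1, 1), length(carriers), replace = TRUE)
    }
    nTot <- cfg$nFemale + cfg$nMale
    se <- 1 / sqrt(2 * truth$maf * (1 - truth$maf) * nTot)
    p <- .pTwoSidedZ(z)
    p[p == 0] <- .Machine$double.xmin
    Sumstats(data.frame(
      snp_id = truth$snp_id, chrom = truth$chrom, pos = truth$pos,
      effect_allele = "A", other_allele = "G", eaf = truth$maf,
      beta = z * se, se = se, pvalue = p, n = nTot,
      stringsAsFactors = FALSE), trait = trait, stratum = "combined")
  })
}

#' Simulate annotation resources with known ground truth
#'
#' Builds gene models tiled along the synthetic genome, a bimodal pLI
#' table, gene sets (random plus sex-het-specific sets that oversample
#' genes near planted sex-het SNPs), meQTL and predicted-eQTL maps with a
#' configurable sex-het membership excess, regulatory interval annotations
#' of configurable genome coverage, and the block-diagonal LD provider
#' matching the simulated noise correlation.
#'
#' @param cfg A `"SimConfig"`.
#' @param truth Truth table from [simulateSumstats()].
#' @param seed Seed (default derived from `cfg$seed`).
#' @return List with `models` ([GeneModels-class]), `pli`, `geneSets`,
#'   `intervals` (named list of `GRanges`), `meqtl`, `preqtl`
#'   (`data.frame`s), `ld` ([LDProvider-class]) and `nearestGene`
#'   (`data.frame` mapping every SNP to its nearest gene and distance).
#' @export
simulateAnnotations <- function(cfg, truth, seed = cfg$seed + 20000L) {
  stopifnot(inherits(cfg, "SimConfig"))
  .withSeed(seed, {
    step <- cfg$geneLength + cfg$geneGap
    chroms <- unique(truth$chrom)
    geneRows <- lapply(chroms, function(ch) {
      span <- range(truth$pos[truth$chrom == ch])
      starts <- seq(span[1], span[2], by = step)
      data.frame(chrom = ch, start = starts, end = starts + cfg$geneLength - 1,
                 stringsAsFactors = FALSE)
    })
    gd <- do.call(rbind, geneRows)
    gd$gene_id <- sprintf("GENE%05d", seq_len(nrow(gd)))
    genes <- GRanges(gd$chrom, IRanges(gd$start, gd$end))
    mcols(genes)$gene_id <- gd$gene_id

    # exons evenly spaced inside each gene; the first 300 bp are UTR
    exLen <- floor(cfg$geneLength / (2 * cfg$exonsPerGene))
    exOff <- round(seq(0, cfg$geneLength - exLen, length.out = cfg$exonsPerGene))
    exons <- GRanges(rep(gd$chrom, each = cfg$exonsPerGene),
                     IRanges(rep(gd$start, each = cfg$exonsPerGene) +
                               rep(exOff, nrow(gd)),
                             width = exLen))
    mcols(exons)$gene_id <- rep(gd$gene_id, each = cfg$exonsPerGene)
    utrs <- GRanges(gd$chrom, IRanges(gd$start, width = 300))
    mcols(utrs)$gene_id <- gd$gene_id
    models <- GeneModels(genes = genes, exons = exons, utrs = utrs)

    high <- runif(nrow(gd)) < cfg$pliHighFrac
    pli <- setNames(ifelse(high, rbeta(nrow(gd), 5, 0.5),
                           rbeta(nrow(gd), 0.5, 5)), gd$gene_id)

    snpGr <- GRanges(truth$chrom, IRanges(truth$pos, truth$pos))
    nh <- distanceToNearest(snpGr, genes)
    nearestGene <- data.frame(
      snp_id = truth$snp_id[queryHits(nh)],
      gene = gd$gene_id[subjectHits(nh)],
      distance = mcols(nh)$distance, stringsAsFactors = FALSE)

    hetGenes <- unique(nearestGene$gene[
      nearestGene$snp_id %in% truth$snp_id[truth$is_sexhet] &
        nearestGene$distance <= 25000])
    p0 <- cfg$geneSetBaseline
    nSpecific <- max(1L, floor(cfg$nGeneSets / 3))
    geneSets <- list()
    for (k in seq_len(cfg$nGeneSets)) {
      if (k <= nSpecific) {
        pr <- ifelse(gd$gene_id %in% hetGenes,
                     pmin(1, p0 * cfg$geneSetSexhetExcess), p0)
        geneSets[[sprintf("set_sexhet%02d", k)]] <-
          gd$gene_id[runif(nrow(gd)) < pr]
      } else {
        geneSets[[sprintf("set_random%02d", k - nSpecific)]] <-
          gd$gene_id[runif(nrow(gd)) < p0]
      }
    }

    isHet <- truth$is_sexhet
    member <- function(frac, excess) {
      runif(nrow(truth)) < ifelse(isHet, pmin(1, frac * excess), frac)
    }
    meSnps <- which(member(cfg$meqtlFrac, cfg$meqtlSexhetExcess))
    meRows <- rep(meSnps, 1 + rpois(length(meSnps), 1.2))
    meqtl <- data.frame(
      snp = truth$snp_id[meRows],
      cpg = sprintf("cg%07d", sample.int(10 * max(1, length(meRows)),
                                         length(meRows))),
      p = 10^-runif(length(meRows), 8, 30),
      tissue = sample(c("cord_blood", "maternal_blood"), length(meRows),
                      replace = TRUE), stringsAsFactors = FALSE)

    prSnps <- which(member(cfg$preqtlFrac, cfg$preqtlSexhetExcess))
    prRows <- rep(prSnps, 1 + rpois(length(prSnps), 0.8))
    brain <- runif(length(prRows)) < cfg$preqtlBrainShare
    tissue <- ifelse(brain, paste0("brain_", sample.int(13, length(prRows),
                                                        replace = TRUE)),
                     paste0("tissue_", sample.int(36, length(prRows),
                                                  replace = TRUE)))
    nearIdx <- match(truth$snp_id[prRows], nearestGene$snp_id)
    egene <- ifelse(runif(length(prRows)) < 0.5, nearestGene$gene[nearIdx],
                    sample(gd$gene_id, length(prRows), replace = TRUE))
    preqtl <- data.frame(snp = truth$snp_id[prRows], egene = egene,
                         tissue = tissue, stringsAsFactors = FALSE)

    intervals <- list()
    spanByChrom <- lapply(chroms, function(ch)
      range(truth$pos[truth$chrom == ch]))
    names(spanByChrom) <- chroms
    intLen <- 5000
    for (k in seq_len(cfg$nRegulatory)) {
      rows <- lapply(chroms, function(ch) {
        span <- spanByChrom[[ch]]
        nInt <- max(1, round(cfg$regulatoryCoverage * diff(span) / intLen))
        st <- sort(sample.int(max(1, diff(span) - intLen), nInt)) + span[1]
        data.frame(chrom = ch, start = st, end = st + intLen - 1)
      })
      rd <- do.call(rbind, rows)
      intervals[[sprintf("annot%02d", k)]] <-
        reduce(GRanges(rd$chrom, IRanges(rd$start, rd$end)))
    }

    ld <- ldFromBlocks(setNames(truth$block, truth$snp_id),
                       r2Within = cfg$ldR2Within)
    list(models = models, pli = pli, geneSets = geneSets,
         intervals = intervals, meqtl = meqtl, preqtl = preqtl, ld = ld,
         nearestGene = nearestGene)
  })
}
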