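#' @include AllClasses.R synthetic-data.R het-stats.R multitrait-meta.R
#' @include ld-clump.R matched-null.R enrichment.R gene-annotation.R ora.R
NULL

.defaultPipelineParams <- function() {
  list(p_threshold = 5e-8, maf_min = 0.001, r2_threshold = 0.2,
       n_null_sets = 100, alpha = 0.05, use_overlap_correction = FALSE,
       null_band = 1, n_diseases = 2, disease_scenario = "pleiotropic",
       gene_cutoff = 25000, seed = 1)
}

.validatePipelineConfig <- function(config) {
  if (!is.list(config)) stop("config must be a list or a YAML file path")
  known <- c("outdir", "params", "sim", "stages")
  bad <- setdiff(names(config), known)
  if (length(bad)) {
    stop("unknown config key(s): ", paste(bad, collapse = ", "))
  }
  if (is.null(config$outdir)) stop("config$outdir is required")
  config$params <- modifyList(.defaultPipelineParams(),
                              as.list(config$params))
  config$sim <- as.list(config$sim)
  if (is.null(config$stages)) {
    config$stages <- c("simulate", "discover", "meta", "clump", "match",
                       "enrich", "annotate", "ora")
  }
  config
}

#' Run the full sex-het discovery and enrichment pipeline
#'
#' Orchestrates the stages of the analysis from one configuration:
#' simulate (synthetic inputs with known truth), discover (per-trait
#' heterogeneity statistics), meta (cross-trait meta-analysis and
#' candidate union), clump (independent tag catalog), match (null-set
#' sampling), enrich (disease signal, interval, meQTL and Pr-eQTL
#' overlaps), annotate (gene assignment and constraint check) and ora
#' (gene-set overrepresentation with empirical calibration). Stage outputs
#' are written as TSV under `outdir` and a reproducibility manifest
#' (config hash, seeds, per-file checksums, stage timings, package
#' version) is written as `manifest.yaml`. Dropping a stage from
#' `config$stages` skips it and everything that depends on its outputs,
#' with a log notice.
#'
#' @param config Named list (or path to a YAML file) with keys `outdir`,
#'   `params` (see Details), `sim` ([simConfig()] overrides) and optional
#'   `stages` (character subset of the stage names above, in order).
#' @return The manifest, invisibly; all results are in `outdir`.
#' @export
runPipeline <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  config <- .validatePipelineConfig(config)
  params <- config$params
  outdir <- config$outdir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  stages <- config$stages
  manifest <- list(
    version = as.character(packageVersion("sexhet")),
    # hash over the analysis-relevant configuration (output location excluded)
    config_hash = unname(md5sum(local({
      f <- tempfile()
      yaml::write_yaml(config[setdiff(names(config), "outdir")], f)
      f
    }))),
    seed = params$seed, stages = list(), files = list())
  t0 <- proc.time()[["elapsed"]]
  mark <- function(stage) {
    t1 <- proc.time()[["elapsed"]]
    manifest$stages[[stage]] <<- round(t1 - t0, 3)
    t0 <<- t1
  }
  save <- function(obj, name) {
    path <- file.path(outdir, name)
    fwrite(obj, path, sep = "\t")
    manifest$files[[name]] <<- unname(md5sum(path))
    path
  }
  has <- function(stage) stage %in% stages

  cfg <- do.call(simConfig, modifyList(config$sim,
                                       list(seed = params$seed)))
  if (!has("simulate")) {
    .sexhetLog("runPipeline: 'simulate' stage disabled; nothing to do")
    return(invisible(manifest))
  }
  sim <- simulateSumstats(cfg)
  ann <- simulateAnnotations(cfg, sim$truth)
  save(sim$truth, "truth.tsv")
  mark("simulate")

  if (!has("discover")) return(invisible(.finishManifest(manifest, outdir)))
  paired <- lapply(sim$sumstats, function(tr)
    harmonizePair(tr$female, tr$male))
  hetList <- lapply(paired, hetStats)
  lambda <- vapply(hetList, function(h) genomicInflation(chisq = h$q_stat),
                   numeric(1))
  save(data.frame(trait = names(lambda), lambda = lambda), "lambda.tsv")
  for (tr in names(hetList)) {
    save(hetList[[tr]], sprintf("het_%s.tsv", tr))
  }
  mark("discover")

  if (!has("meta")) return(invisible(.finishManifest(manifest, outdir)))
  corr <- NULL
  if (isTRUE(params$use_overlap_correction) && length(hetList) >= 2) {
    snps <- hetList[[1]]$snp_id
    # overlap correlation is estimated on the signed meta inputs
    zM <- vapply(hetList, function(h) {
      i <- match(snps, h$snp_id)
      s <- signedInput(h$beta_het[i], h$se_het[i], h$beta_f[i], h$beta_m[i])
      s$beta / s$se
    }, numeric(length(snps)))
    corr <- estimateOverlapCorr(zM, nullBand = params$null_band)
  }
  meta <- metaFixedTable(hetList, corr = corr)
  save(meta, "meta.tsv")
  candidates <- combineUniMulti(hetList, meta,
                                pThreshold = params$p_threshold,
                                mafMin = params$maf_min)
  save(candidates, "candidates.tsv")
  mark("meta")

  if (!has("clump") || !nrow(candidates)) {
    if (!nrow(candidates)) .sexhetLog("runPipeline: no candidate SNPs; stopping after meta")
    return(invisible(.finishManifest(manifest, outdir)))
  }
  catalog <- clumpSnps(candidates, ann$ld, r2Threshold = params$r2_threshold)
  save(catalog@data, "catalog.tsv")
  mark("clump")

  nulls <- NULL
  if (has("match")) {
    # pool = the first trait's harmonized pair (leading-trait convention)
    index <- buildMatchingIndex(paired[[1]], catalog, ann$ld)
    nulls <- sampleMatchedSets(index, nSets = params$n_null_sets,
                               seed = params$seed)
    writeNullSets(nulls, file.path(outdir, "null_sets"))
    mark("match")
  }

  if (has("enrich")) {
    if (is.null(nulls)) {
      .sexhetLog("runPipeline: 'match' stage skipped; enrichment reported without empirical p-values")
    }
    rows <- lapply(seq_len(params$n_diseases), function(k) {
      dz <- simulateDisease(cfg, sim$truth, scenario = params$disease_scenario,
                            seed = params$seed + 10000L + k,
                            trait = paste0("disease", k))
      er <- signalEnrichment(catalog, dz, alpha = params$alpha,
                             nullSets = nulls)
      data.frame(disease = paste0("disease", k), n_overlap = er@nOverlap,
                 observed_pct = er@observedStat,
                 expected_count = er@expectedCount,
                 chi2_p = er@chi2P, emp_p = er@empP)
    })
    save(do.call(rbind, rows), "disease_enrichment.tsv")
    meSig <- unique(ann$meqtl$snp[ann$meqtl$p < 1e-14])
    me <- snpsetOverlap(catalog, meSig,
                        perSnpItems = data.frame(snp = ann$meqtl$snp,
                                                 item = ann$meqtl$cpg),
                        nullSets = nulls)
    pr <- snpsetOverlap(catalog, unique(ann$preqtl$snp),
                        perSnpItems = data.frame(snp = ann$preqtl$snp,
                                                 item = ann$preqtl$egene),
                        nullSets = nulls)
    save(data.frame(
      target = c("meqtl", "preqtl"),
      n_overlap = c(me@nOverlap, pr@nOverlap),
      pct = c(me@observedStat, pr@observedStat),
      n_items = c(me@items$n_items, pr@items$n_items),
      emp_p = c(me@empP, pr@empP)), "qtl_overlap.tsv")
    save(intervalOverlap(catalog, ann$intervals, nullSets = nulls,
                         pool = sim$truth), "regulatory_overlap.tsv")
    mark("enrich")
  }

  assignments <- NULL
  if (has("annotate")) {
    assignments <- annotateSnps(catalog, ann$models,
                                cutoff = params$gene_cutoff)
    save(assignments, "gene_assignments.tsv")
    genes <- assignedGenes(assignments)
    if (length(genes)) {
      save(constraintEnrichment(genes, ann$pli), "constraint.tsv")
    }
    save(distanceRatioDiagnostic(assignments), "distance_ratio.tsv")
    mark("annotate")
  }

  if (has("ora") && !is.null(assignments) && !is.null(nulls)) {
    universe <- names(ann$pli)
    obs <- oraTest(assignedGenes(assignments), ann$geneSets,
                   universe = universe)
    permLists <- lapply(nulls[seq_len(min(100, length(nulls)))], function(s) {
      assignedGenes(annotateSnps(
        sim$truth[match(s@snps, sim$truth$snp_id), ], ann$models,
        cutoff = params$gene_cutoff))
    })
    obs <- oraEmpirical(obs, permLists, ann$geneSets, universe = universe)
    save(obs, "ora.tsv")
    mark("ora")
  }

  invisible(.finishManifest(manifest, outdir))
}

.finishManifest <- function(manifest, outdir) {
  yaml::write_yaml(manifest, file.path(outdir, "manifest.yaml"))
  manifest
}
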