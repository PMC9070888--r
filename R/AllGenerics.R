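#' @include AllClasses.R
NULL

#' SNP identifiers stored in an object
#' @param x A sexhet container.
#' @return Character vector of SNP ids.
#' @export
setGeneric("snpIds", function(x) standardGeneric("snpIds"))

#' Underlying data.frame of a sexhet container
#' @param x A sexhet container.
#' @return The `data.frame` held by the object.
#' @export
setGeneric("tbl", function(x) standardGeneric("tbl"))

#' Pairwise LD r-squared lookup
#' @param x An [LDProvider-class].
#' @param a,b SNP id vectors of equal length (or length 1, recycled).
#' @return Numeric vector of r-squared values; unknown pairs are 0.
#' @export
setGeneric("ldR2", function(x, a, b) standardGeneric("ldR2"))

#' LD neighbors of a SNP above an r-squared threshold
#' @param x An [LDProvider-class].
#' @param snp A single SNP id.
#' @param r2Min Minimum r-squared (exclusive lower bound is not applied;
#'   neighbors with `r2 >= r2Min` are returned).
#' @return Character vector of neighbor SNP ids (never includes `snp`).
#' @export
setGeneric("ldNeighbors", function(x, snp, r2Min = 0.2) standardGeneric("ldNeighbors"))

setMethod("snpIds", "Sumstats", function(x) x@data$snp_id)
setMethod("snpIds", "PairedSumstats", function(x) x@data$snp_id)
setMethod("snpIds", "SexHetCatalog", function(x) x@data$snp_id)
setMethod("snpIds", "MatchedNullSet", function(x) x@snps)

setMethod("tbl", "Sumstats", function(x) x@data)
setMethod("tbl", "PairedSumstats", function(x) x@data)
setMethod("tbl", "SexHetCatalog", function(x) x@data)
setMethod("tbl", "MatchedNullSet", function(x) x@meta)

setMethod("length", "Sumstats", function(x) nrow(x@data))
setMethod("length", "PairedSumstats", function(x) nrow(x@data))
setMethod("length", "SexHetCatalog", function(x) nrow(x@data))
setMethod("length", "MatchedNullSet", function(x) length(x@snps))

setMethod("show", "Sumstats", function(object) {
  cat(sprintf("Sumstats: %d SNPs (trait='%s', stratum='%s', %d rows dropped)\n",
              nrow(object@data), object@trait, object@stratum, object@nDropped))
})

setMethod("show", "PairedSumstats", function(object) {
  cat(sprintf("PairedSumstats: %d SNPs (trait='%s'; dropped: %s)\n",
              nrow(object@data), object@trait,
              paste(names(object@nDropped), object@nDropped,
                    sep = "=", collapse = ", ")))
})

setMethod("show", "LDProvider", function(object) {
  cat(sprintf("LDProvider: %d SNPs with stored neighbors\n",
              length(ls(object@neighbors))))
})

setMethod("show", "SexHetCatalog", function(object) {
  cat(sprintf("SexHetCatalog: %d independent tag SNPs (r2 < %g)\n",
              nrow(object@data), object@r2Threshold))
  if (nrow(object@data)) {
    print(head(object@data, 5))
    if (nrow(object@data) > 5) cat("...\n")
  }
})

setMethod("show", "MatchedNullSet", function(object) {
  cat(sprintf("MatchedNullSet: %d SNPs (seed %d, %d relaxed entries)\n",
              length(object@snps), object@seed, sum(object@meta$relaxed != 0)))
})

setMethod("show", "EnrichmentResult", function(object) {
  cat(sprintf(
    "EnrichmentResult: n_overlap=%d observed=%.2f%% expected=%.2f%% chi2P=%s empP=%s\n",
    object@nOverlap, object@observedStat, object@expectedStat,
    format(object@chi2P, digits = 3), format(object@empP, digits = 3)))
})

setMethod("show", "GeneModels", function(object) {
  cat(sprintf("GeneModels: %d genes, %d exons, %d UTRs\n",
              length(object@genes), length(object@exons), length(object@utrs)))
})
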