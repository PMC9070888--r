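#' @include AllClasses.R
NULL

#' Read gene models from a GFF3 subset or BED file
#'
#' GFF3 input keeps `gene`, `exon` and UTR features (gene ids from the
#' `ID`/`Parent` attributes or a `gene_id` column); BED input yields gene
#' bodies only (names as gene ids), under which every genic SNP classifies
#' as intronic.
#'
#' @param path File path (`.gff`, `.gff3` or `.bed`).
#' @return A [GeneModels-class] object.
#' @export
readGeneModels <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (grepl("\\.bed(\\.gz)?$", path, ignore.case = TRUE)) {
    gr <- rtracklayer::import(path, format = "BED")
    mcols(gr)$gene_id <- if (!is.null(mcols(gr)$name)) mcols(gr)$name else
      paste0("gene", seq_along(gr))
    return(GeneModels(genes = gr))
  }
  gr <- rtracklayer::import(path, format = "GFF3")
  type <- tolower(as.character(mcols(gr)$type))
  gid <- mcols(gr)$gene_id
  if (is.null(gid)) {
    id <- as.character(mcols(gr)$ID)
    parent <- vapply(as.list(mcols(gr)$Parent), function(x)
      if (length(x)) as.character(x)[1] else NA_character_, character(1))
    gid <- ifelse(type == "gene", id, parent)
  }
  pick <- function(sel) {
    out <- gr[sel]
    mcols(out) <- NULL
    mcols(out)$gene_id <- as.character(gid[sel])
    out
  }
  GeneModels(genes = pick(type == "gene"),
             exons = pick(type == "exon"),
             utrs = pick(grepl("utr", type)))
}

# splice-site windows: +/- spliceBp around internal exon boundaries
.spliceSites <- function(models, spliceBp = 2) {
  ex <- models@exons
  if (!length(ex)) return(GRanges())
  genes <- models@genes
  gidx <- match(mcols(ex)$gene_id, mcols(genes)$gene_id)
  bStart <- start(ex); bEnd <- end(ex)
  internalStart <- bStart != start(genes)[gidx]
  internalEnd <- bEnd != end(genes)[gidx]
  pos <- c(bStart[internalStart], bEnd[internalEnd])
  gid <- c(mcols(ex)$gene_id[internalStart], mcols(ex)$gene_id[internalEnd])
  chr <- c(as.character(seqnames(ex))[internalStart],
           as.character(seqnames(ex))[internalEnd])
  if (!length(pos)) return(GRanges())
  out <- GRanges(chr, IRanges(pmax(1, pos - spliceBp), pos + spliceBp))
  mcols(out)$gene_id <- gid
  out
}

#' Assign genes to SNPs (genic classes and the 25 kb nearest-gene rule)
#'
#' Genic SNPs are classified by feature containment with priority
#' splicing > UTR > exonic > intronic (splice sites are the ±`spliceBp`
#' windows around internal exon boundaries; a SNP inside a gene body but
#' outside any exon — or when no exon structure is available — is
#' intronic). Intergenic SNPs are assigned their nearest gene when the
#' distance to the nearest transcript boundary is at most `cutoff`
#' (default 25 kb), and left unassigned otherwise. The second flanking
#' gene (`gene_b`) and both distances are reported for the distance-ratio
#' diagnostic; it never contributes to the assignment.
#'
#' @param snps `data.frame` with `snp_id`, `chrom`, `pos` (a
#'   [SexHetCatalog-class] is also accepted).
#' @param models A [GeneModels-class] object.
#' @param cutoff Maximum SNP-to-gene distance for intergenic assignment,
#'   in bp (default 25000).
#' @param spliceBp Splice-site half-window in bp (default 2).
#' @return `data.frame` with `snp_id`, `genic_class`, `gene`,
#'   `distance_bp`, `gene_a`, `gene_b`, `dist_a`, `dist_b`.
#' @export
annotateSnps <- function(snps, models, cutoff = 25000, spliceBp = 2) {
  if (is(snps, "SexHetCatalog")) snps <- snps@data
  .stopifnotCols(snps, c("snp_id", "chrom", "pos"), "snps")
  stopifnot(is(models, "GeneModels"))
  gr <- GRanges(snps$chrom, IRanges(snps$pos, snps$pos))
  genes <- models@genes
  n <- nrow(snps)
  cls <- rep("intergenic", n)
  gene <- rep(NA_character_, n)
  dist <- rep(NA_real_, n)

  assignClass <- function(feat, label) {
    if (!length(feat)) return()
    hits <- findOverlaps(gr, feat)
    qi <- queryHits(hits)
    upgrade <- .CLASS_PRIORITY[label] < .CLASS_PRIORITY[cls[qi]]
    qi <- qi[upgrade]
    if (!length(qi)) return()
    first <- !duplicated(qi)
    cls[qi[first]] <<- label
    gene[qi[first]] <<- as.character(mcols(feat)$gene_id[subjectHits(hits)[upgrade][first]])
    dist[qi[first]] <<- 0
  }
  # apply lowest priority first so higher priorities overwrite
  assignClass(genes, "intronic")
  assignClass(models@exons, "exonic")
  assignClass(models@utrs, "utr")
  assignClass(.spliceSites(models, spliceBp), "splicing")

  multi <- countOverlapsGenes(gr, genes)
  if (any(multi > 1)) {
    .sexhetLog(sprintf("annotateSnps: %d SNPs overlap >1 gene; kept the highest-priority single assignment",
                       sum(multi > 1)))
  }

  # flanking genes for intergenic SNPs (strand-ignorant, gene-body anchors)
  inter <- which(cls == "intergenic")
  geneA <- geneB <- rep(NA_character_, n)
  distA <- distB <- rep(NA_real_, n)
  if (length(inter)) {
    gi <- gr[inter]
    up <- follow(gi, genes, ignore.strand = TRUE)    # nearest gene left of SNP
    dn <- precede(gi, genes, ignore.strand = TRUE)   # nearest gene right of SNP
    dUp <- ifelse(is.na(up), Inf, start(gi) - end(genes)[up])
    dDn <- ifelse(is.na(dn), Inf, start(genes)[dn] - start(gi))
    aIsUp <- dUp <= dDn
    ai <- ifelse(aIsUp, up, dn)
    bi <- ifelse(aIsUp, dn, up)
    distA[inter] <- pmin(dUp, dDn)
    distB[inter] <- pmax(dUp, dDn)
    geneA[inter] <- ifelse(is.na(ai), NA,
                           as.character(mcols(genes)$gene_id)[ai])
    geneB[inter] <- ifelse(is.na(bi), NA,
                           as.character(mcols(genes)$gene_id)[bi])
    assign_ <- is.finite(distA[inter]) & distA[inter] <= cutoff
    gene[inter[assign_]] <- geneA[inter[assign_]]
    dist[inter[assign_]] <- distA[inter[assign_]]
    distB[!is.finite(distB)] <- NA
    distA[!is.finite(distA)] <- NA
  }

  data.frame(snp_id = snps$snp_id, genic_class = cls, gene = gene,
             distance_bp = dist, gene_a = geneA, gene_b = geneB,
             dist_a = distA, dist_b = distB, stringsAsFactors = FALSE)
}

.CLASS_PRIORITY <- c(splicing = 1, utr = 2, exonic = 3, intronic = 4,
                     intergenic = 5)

countOverlapsGenes <- function(gr, genes) {
  GenomicRanges::countOverlaps(gr, genes)
}

#' Gene list mapped to a SNP set
#'
#' Unique genes assigned by [annotateSnps()] (genic assignments plus
#' intergenic assignments within the distance cutoff).
#'
#' @param assignments Output of [annotateSnps()].
#' @return Character vector of gene ids.
#' @export
assignedGenes <- function(assignments) {
  sort(unique(assignments$gene[!is.na(assignments$gene)]))
}

#' Flanking-gene distance-ratio diagnostic
#'
#' For intergenic SNPs with both flanking genes known, counts per distance
#' bin how many SNPs have their nearest gene (`gene_a`) within the bin
#' versus their second flanking gene (`gene_b`), and reports the ratio.
#' A rapidly decaying ratio beyond the first bin motivates the 25 kb
#' assignment cutoff.
#'
#' @param assignments Output of [annotateSnps()].
#' @param binsKb Bin edges in kb (default `c(0, 25, 50, 100, 200, 500, 2000)`).
#' @return `data.frame` with `bin`, `n_gene_a`, `n_gene_b`, `ratio`
#'   (`NA` when the `gene_b` count is zero).
#' @export
distanceRatioDiagnostic <- function(assignments,
                                    binsKb = c(0, 25, 50, 100, 200, 500, 2000)) {
  a <- assignments[assignments$genic_class == "intergenic" &
                     !is.na(assignments$dist_a) & !is.na(assignments$dist_b), ]
  edges <- binsKb * 1000
  labs <- paste0(binsKb[-length(binsKb)], "-", binsKb[-1], "kb")
  cutA <- cut(a$dist_a, edges, labels = labs, include.lowest = TRUE)
  cutB <- cut(a$dist_b, edges, labels = labs, include.lowest = TRUE)
  nA <- as.integer(table(cutA))
  nB <- as.integer(table(cutB))
  data.frame(bin = labs, n_gene_a = nA, n_gene_b = nB,
             ratio = ifelse(nB > 0, nA / nB, NA_real_),
             stringsAsFactors = FALSE)
}

#' Constraint (pLI) enrichment of a gene list
#'
#' Observed fractions of the gene list in the highly-constrained
#' (`pLI > 0.9`) and non-constrained (`pLI < 0.1`) bins, tested against
#' user-supplied reference proportions with exact binomial tests. Genes
#' without a pLI value are excluded.
#'
#' @param genes Character vector of gene ids.
#' @param pli Named numeric vector of pLI scores (from [readPli()]).
#' @param reference Named numeric vector with reference fractions `high`
#'   (pLI > 0.9) and `low` (pLI < 0.1), e.g. from a population reference
#'   database.
#' @return `data.frame` with rows `high`/`low`: `n_genes`, `n_in_bin`,
#'   `observed_fraction`, `reference_fraction`, `binom_p` (two-sided).
#' @export
constraintEnrichment <- function(genes, pli,
                                 reference = c(high = 0.18, low = 0.52)) {
  scores <- pli[match(genes, names(pli))]
  scores <- scores[!is.na(scores)]
  if (!length(scores)) stop("no gene in the list has a pLI value")
  n <- length(scores)
  rows <- lapply(c(high = "high", low = "low"), function(b) {
    k <- if (b == "high") sum(scores > 0.9) else sum(scores < 0.1)
    ref <- unname(reference[[b]])
    data.frame(bin = b, n_genes = n, n_in_bin = k,
               observed_fraction = k / n, reference_fraction = ref,
               binom_p = binom.test(k, n, p = ref)$p.value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
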