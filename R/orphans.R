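#' Find taxonomically restricted (orphan) gene clusters
#'
#' \itemize{
#'   \item `level = "genus"`: clusters present in every ingroup species
#'     (strains OR-collapsed) and absent from every outgroup taxon — the
#'     genus-specific orphans, a subset of the core genome.
#'   \item `level = "clade"`: clusters specific to one clade by the
#'     all-but-one rule ([subsetSpecific()] on the clade's taxa), absent
#'     from everything else including outgroups.
#'   \item `level = "species"`: clusters whose members all belong to one
#'     taxon (including unclustered singletons).
#' }
#'
#' @param table a [ClusterTable-class].
#' @param partition a [CladePartition-class]; outgroups must be present in
#'   the table for genus level.
#' @param level `"genus"`, `"clade"` or `"species"`.
#' @param clade clade label (level = "clade").
#' @param taxon taxon id (level = "species").
#' @return list with elements `level`, `clusters` (cluster ids) and `genes`
#'   (named list taxon -> gene ids, when the table has member lists).
#' @export
findOrphans <- function(table, partition, level = c("genus", "clade",
                                                    "species"),
                        clade = NULL, taxon = NULL) {
  level <- match.arg(level)
  og <- intersect(outgroupTaxa(partition), taxonIds(table))
  cts <- clusterCounts(table)
  cl <- switch(level,
    genus = {
      if (!length(og)) stop("genus level needs outgroup taxa in the table")
      core <- coreClusters(table, partition)
      noOut <- rownames(cts)[rowSums(cts[, og, drop = FALSE] >= 1L) == 0L]
      intersect(core, noOut)
    },
    clade = {
      if (is.null(clade)) stop("clade level needs a clade label")
      tx <- intersect(cladeTaxa(partition, clade), taxonIds(table))
      if (!length(tx)) stop("no table taxa in clade ", clade)
      subsetSpecific(table, tx)
    },
    species = {
      if (is.null(taxon)) stop("species level needs a taxon")
      if (!taxon %in% taxonIds(table)) stop("unknown taxon: ", taxon)
      pres <- cts >= 1L
      rownames(cts)[pres[, taxon] &
                      rowSums(pres[, setdiff(colnames(cts), taxon),
                                   drop = FALSE]) == 0L]
    })
  genes <- NULL
  mem <- clusterMembers(table)
  if (length(mem)) {
    mm <- do.call(rbind, mem[cl])
    if (!is.null(mm) && nrow(mm))
      genes <- split(mm$protein, mm$taxon)
  }
  list(level = level, clusters = cl, genes = genes)
}

#' Chromosomal runs of orphan genes
#'
#' A cluster is a maximal run of two or more genes, consecutive in the gene
#' order along a chromosome, that are all orphans; `maxGap` intervening
#' non-orphan genes are tolerated inside a run when `maxGap > 0` (default 0:
#' strictly adjacent). Remaining orphans are singletons. Orphan ids absent
#' from the gene map are dropped with a warning and listed in the report.
#'
#' @param genemap a [GeneMap-class].
#' @param orphanIds gene ids of orphans.
#' @param maxGap tolerated non-orphan genes inside a run (default 0).
#' @return list with `clusters` (data.frame: chrom, first_ordinal, size),
#'   `singletons` (gene ids), `sizeHistogram` (named integer vector by run
#'   size, size 1 = singletons) and `missing` (unmappable ids).
#' @export
orphanRuns <- function(genemap, orphanIds, maxGap = 0L) {
  gr <- geneLoci(genemap)
  missing <- setdiff(orphanIds, names(gr))
  if (length(missing))
    warning("orphan id(s) missing from gene map: ",
            paste(missing, collapse = ", "))
  orphanIds <- setdiff(orphanIds, missing)
  chrom <- as.character(GenomicRanges::seqnames(gr))
  ord <- S4Vectors::mcols(gr)$ordinal
  isOrf <- names(gr) %in% orphanIds
  clusters <- list(); singles <- character()
  for (ch in unique(chrom)) {
    i <- chrom == ch
    o <- order(ord[i])
    flags <- isOrf[i][o]
    ids <- names(gr)[i][o]
    ords <- ord[i][o]
    pos <- which(flags)
    if (!length(pos)) next
    # group orphan positions whose gaps (non-orphans between) are <= maxGap
    grp <- cumsum(c(1L, diff(pos) > (maxGap + 1L)))
    for (g in split(pos, grp)) {
      if (length(g) >= 2L) {
        clusters[[length(clusters) + 1L]] <-
          data.frame(chrom = ch, first_ordinal = ords[g[1L]],
                     size = length(g), stringsAsFactors = FALSE)
      } else singles <- c(singles, ids[g])
    }
  }
  clusters <- if (length(clusters)) do.call(rbind, clusters) else
    data.frame(chrom = character(), first_ordinal = integer(),
               size = integer(), stringsAsFactors = FALSE)
  sizes <- c(rep(1L, length(singles)), clusters$size)
  hist <- table(factor(sizes, levels = sort(unique(sizes))))
  list(clusters = clusters, singletons = singles,
       sizeHistogram = stats::setNames(as.integer(hist), names(hist)),
       missing = missing)
}

#' Fraction of genes in subtelomeric windows
#'
#' A gene is subtelomeric iff its midpoint `(start + end) / 2` lies within
#' `windowBp` of either chromosome end (distance to end =
#' `min(midpoint, length - midpoint)`).
#'
#' @param genemap a [GeneMap-class] with chromosome lengths.
#' @param geneIds genes to classify (default all).
#' @param windowBp window size in bp (default 100000).
#' @return list with `fraction`, `n_subtelomeric`, `n_total` and `perGene`
#'   (data.frame: gene_id, chrom, midpoint, dist_to_end, class).
#' @export
subtelomericFraction <- function(genemap, geneIds = NULL, windowBp = 1e5) {
  stopifnot(windowBp >= 0)
  gr <- geneLoci(genemap)
  if (is.null(geneIds)) geneIds <- names(gr)
  missing <- setdiff(geneIds, names(gr))
  if (length(missing))
    stop("gene id(s) missing from gene map: ", paste(missing, collapse = ", "))
  gr <- gr[geneIds]
  sl <- GenomeInfoDb::seqlengths(gr)
  chrom <- as.character(GenomicRanges::seqnames(gr))
  if (any(is.na(sl[chrom])))
    stop("missing chromosome length for: ",
         paste(unique(chrom[is.na(sl[chrom])]), collapse = ", "))
  mid <- (GenomicRanges::start(gr) + GenomicRanges::end(gr)) / 2
  dist <- pmin(mid, sl[chrom] - mid)
  sub <- dist <= windowBp
  list(fraction = if (length(sub)) mean(sub) else NaN,
       n_subtelomeric = sum(sub), n_total = length(sub),
       perGene = data.frame(gene_id = names(gr), chrom = chrom,
                            midpoint = mid, dist_to_end = unname(dist),
                            class = ifelse(sub, "subtelomeric", "middle"),
                            stringsAsFactors = FALSE, row.names = NULL))
}
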