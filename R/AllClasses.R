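#' @import methods
#' @importFrom S4Vectors mcols mcols<-
#' @importClassesFrom Biostrings AAStringSet
#' @importClassesFrom GenomicRanges GRanges
NULL

AA_ALPHABET20 <- c("A","R","N","D","C","Q","E","G","H","I",
                   "L","K","M","F","P","S","T","W","Y","V")
AA_VALID <- c(AA_ALPHABET20, "X")

#' Proteome: the predicted protein complement of one taxon
#'
#' Wraps a [Biostrings::AAStringSet] of amino-acid sequences (20-letter
#' alphabet plus `X` for unknown residues) together with the taxon identifier.
#' Protein identifiers (the `names()` of the set) must be unique within the
#' taxon and every sequence must be non-empty.
#'
#' @slot taxon single taxon identifier.
#' @slot aa an `AAStringSet`, names are protein ids.
#' @export
setClass("Proteome", representation(taxon = "character", aa = "AAStringSet"))

setValidity("Proteome", function(object) {
  msg <- character()
  if (length(object@taxon) != 1L || is.na(object@taxon) || !nzchar(object@taxon))
    msg <- c(msg, "taxon must be a single non-empty string")
  ids <- names(object@aa)
  if (length(object@aa) > 0L) {
    if (is.null(ids) || any(!nzchar(ids)))
      msg <- c(msg, "all proteins must be named")
    dup <- ids[duplicated(ids)]
    if (length(dup))
      msg <- c(msg, paste0("duplicate protein id(s): ",
                           paste(unique(dup), collapse = ", ")))
    w <- Biostrings::width(object@aa)
    if (any(w == 0L))
      msg <- c(msg, paste0("empty sequence for: ",
                           paste(ids[w == 0L], collapse = ", ")))
  }
  if (length(msg)) msg else TRUE
})

#' Construct a Proteome
#'
#' @param taxon taxon identifier.
#' @param sequences named character vector or `AAStringSet` of amino-acid
#'   sequences; names are protein ids. Sequences are uppercased.
#' @return a [Proteome-class] object.
#' @examples
#' p <- Proteome("T_reesei", c(p1 = "MKC", p2 = "MM"))
#' nProteins(p)
#' @export
Proteome <- function(taxon, sequences) {
  if (is.character(sequences)) {
    sequences <- toupper(sequences)
    bad <- grepl("[^A-Z]", sequences)
    if (any(bad))
      stop("whitespace or non-letter characters in sequence(s): ",
           paste(names(sequences)[bad], collapse = ", "))
    aa <- Biostrings::AAStringSet(sequences)
  } else {
    aa <- Biostrings::AAStringSet(sequences)
  }
  new("Proteome", taxon = as.character(taxon), aa = aa)
}

#' ClusterTable: ortholog clusters as a taxon-by-cluster count matrix
#'
#' The central object of the package. Rows of `counts` are clusters, columns
#' are taxa; `counts[c, t]` is the number of genes of taxon `t` in cluster
#' `c`. `members` optionally stores per-cluster gene membership as a list of
#' two-column data frames (`taxon`, `protein`); a table built from a counts
#' matrix alone (counts-only mode) has an empty member list and supports all
#' presence/absence operations.
#'
#' @slot counts integer matrix, clusters x taxa, with dimnames.
#' @slot members named list (by cluster id) of data.frames with columns
#'   `taxon` and `protein`, or an empty list.
#' @export
setClass("ClusterTable",
         representation(counts = "matrix", members = "list"))

setValidity("ClusterTable", function(object) {
  msg <- character()
  cts <- object@counts
  if (is.null(rownames(cts)) || is.null(colnames(cts)))
    msg <- c(msg, "counts must have cluster ids as rownames and taxa as colnames")
  if (any(cts < 0) || any(cts != round(cts)))
    msg <- c(msg, "counts must be non-negative integers")
  if (anyDuplicated(rownames(cts)))
    msg <- c(msg, "duplicate cluster ids")
  if (anyDuplicated(colnames(cts)))
    msg <- c(msg, "duplicate taxon ids")
  if (length(object@members)) {
    if (!identical(sort(names(object@members)), sort(rownames(cts))))
      msg <- c(msg, "members must be named by cluster id, one entry per cluster")
    else {
      for (cid in rownames(cts)) {
        m <- object@members[[cid]]
        tab <- table(factor(m$taxon, levels = colnames(cts)))
        if (!all(as.integer(tab) == as.integer(cts[cid, ])))
          { msg <- c(msg, paste0("member/count mismatch in cluster ", cid)); break }
      }
      allm <- do.call(rbind, object@members)
      if (!is.null(allm) && nrow(allm)) {
        key <- paste(allm$taxon, allm$protein, sep = "\r")
        dup <- key[duplicated(key)]
        if (length(dup))
          msg <- c(msg, paste0("protein assigned to more than one cluster: ",
                               gsub("\r", "|", dup[1L])))
      }
    }
  }
  if (length(msg)) msg else TRUE
})

#' Construct a ClusterTable
#'
#' Either from a counts matrix (clusters x taxa), or from a member list from
#' which counts are tallied.
#'
#' @param counts integer matrix with cluster rownames and taxon colnames.
#' @param members named list of data.frames (`taxon`, `protein`) per cluster.
#' @param taxa optional character vector fixing the taxon set (useful when
#'   some taxa have no members).
#' @return a [ClusterTable-class].
#' @examples
#' m <- rbind(C1 = c(A = 1, B = 2), C2 = c(A = 0, B = 1))
#' tab <- ClusterTable(counts = m)
#' clusterCounts(tab)
#' @export
ClusterTable <- function(counts = NULL, members = NULL, taxa = NULL) {
  if (is.null(counts) && is.null(members))
    stop("provide counts and/or members")
  if (is.null(counts)) {
    taxa <- sort(unique(c(taxa, unlist(lapply(members, `[[`, "taxon")))))
    counts <- matrix(0L, nrow = length(members), ncol = length(taxa),
                     dimnames = list(names(members), taxa))
    for (cid in names(members)) {
      tab <- table(factor(members[[cid]]$taxon, levels = taxa))
      counts[cid, ] <- as.integer(tab)
    }
  }
  storage.mode(counts) <- "integer"
  new("ClusterTable", counts = counts,
      members = if (is.null(members)) list() else members)
}

#' CladePartition: clade assignment, ingroup flags and species map
#'
#' Maps every taxon to a clade label (e.g. the three infrageneric groups
#' SL, HV, ST, or `OUTGROUP`), records which taxa form the ingroup, and maps
#' strain-level taxa to species (several sequenced strains of one species
#' collapse to a single species for core-genome tests).
#'
#' @slot clades named character vector, taxon -> clade label.
#' @slot ingroup character vector of ingroup taxon ids.
#' @slot species named character vector, taxon -> species id.
#' @export
setClass("CladePartition",
         representation(clades = "character", ingroup = "character",
                        species = "character"))

setValidity("CladePartition", function(object) {
  msg <- character()
  if (is.null(names(object@clades)))
    msg <- c(msg, "clades must be a named vector (taxon -> clade)")
  unknown <- setdiff(object@ingroup, names(object@clades))
  if (length(unknown))
    msg <- c(msg, paste0("ingroup taxa without clade assignment: ",
                         paste(unknown, collapse = ", ")))
  og <- names(object@clades)[object@clades == "OUTGROUP"]
  both <- intersect(og, object@ingroup)
  if (length(both))
    msg <- c(msg, paste0("taxa both ingroup and OUTGROUP: ",
                         paste(both, collapse = ", ")))
  if (!all(object@ingroup %in% names(object@species)))
    msg <- c(msg, "every ingroup taxon needs a species assignment")
  if (length(msg)) msg else TRUE
})

#' Construct a CladePartition
#'
#' @param clades named character vector taxon -> clade label; taxa labelled
#'   `"OUTGROUP"` are outgroups.
#' @param ingroup ingroup taxa; defaults to all non-OUTGROUP taxa.
#' @param species named character vector taxon -> species; defaults to
#'   identity (each taxon its own species).
#' @return a [CladePartition-class].
#' @export
CladePartition <- function(clades, ingroup = NULL, species = NULL) {
  if (is.null(ingroup))
    ingroup <- names(clades)[clades != "OUTGROUP"]
  if (is.null(species))
    species <- stats::setNames(names(clades), names(clades))
  new("CladePartition", clades = clades, ingroup = ingroup, species = species)
}

#' GeneMap: ordered gene loci along chromosomes of one taxon
#'
#' Wraps a [GenomicRanges::GRanges] whose names are gene ids, whose seqinfo
#' carries chromosome lengths, and whose metadata column `ordinal` numbers
#' genes 1, 2, ... along each chromosome by start position. Coordinates are
#' 1-based inclusive.
#'
#' @slot taxon taxon identifier.
#' @slot loci a `GRanges` with names (gene ids) and `mcols()$ordinal`.
#' @export
setClass("GeneMap", representation(taxon = "character", loci = "GRanges"))

setValidity("GeneMap", function(object) {
  msg <- character()
  gr <- object@loci
  if (length(gr)) {
    if (is.null(names(gr)) || anyDuplicated(names(gr)))
      msg <- c(msg, "gene ids (names of loci) must be present and unique")
    sl <- GenomeInfoDb::seqlengths(gr)
    if (any(is.na(sl)))
      msg <- c(msg, paste0("missing chromosome length for: ",
                           paste(names(sl)[is.na(sl)], collapse = ", ")))
    else {
      over <- GenomicRanges::end(gr) >
        sl[as.character(GenomicRanges::seqnames(gr))]
      if (any(over))
        msg <- c(msg, paste0("locus beyond chromosome length: ",
                             paste(names(gr)[over], collapse = ", ")))
    }
    if (any(GenomicRanges::start(gr) < 1L))
      msg <- c(msg, "start coordinates must be >= 1 (1-based inclusive)")
    ord <- mcols(gr)$ordinal
    if (is.null(ord))
      msg <- c(msg, "loci must carry an 'ordinal' metadata column")
    else {
      for (ch in GenomeInfoDb::seqlevelsInUse(gr)) {
        i <- as.character(GenomicRanges::seqnames(gr)) == ch
        o <- sort(ord[i])
        if (!identical(as.integer(o), seq_len(sum(i))))
          { msg <- c(msg, paste0("ordinals on ", ch,
                                 " are not consecutive from 1")); break }
        byord <- order(ord[i])
        if (is.unsorted(GenomicRanges::start(gr)[i][byord]))
          { msg <- c(msg, paste0("ordinals on ", ch,
                                 " are not sorted by start")); break }
      }
    }
  }
  if (length(msg)) msg else TRUE
})

#' Construct a GeneMap
#'
#' @param taxon taxon id.
#' @param loci data.frame with columns `gene_id`, `chrom`, `start`, `end`
#'   (1-based inclusive).
#' @param chromLengths named numeric vector of chromosome lengths (bp).
#' @return a [GeneMap-class]; ordinals are assigned by start position within
#'   each chromosome.
#' @examples
#' gm <- GeneMap("T", data.frame(gene_id = c("g1", "g2"), chrom = "chr1",
#'                               start = c(100, 50), end = c(120, 70)),
#'               chromLengths = c(chr1 = 1e6))
#' geneOrdinals(gm)
#' @export
GeneMap <- function(taxon, loci, chromLengths) {
  stopifnot(all(c("gene_id", "chrom", "start", "end") %in% names(loci)))
  loci <- loci[order(loci$chrom, loci$start), , drop = FALSE]
  ord <- stats::ave(loci$start, loci$chrom, FUN = seq_along)
  gr <- GenomicRanges::GRanges(
    seqnames = loci$chrom,
    ranges = IRanges::IRanges(start = loci$start, end = loci$end),
    seqinfo = GenomeInfoDb::Seqinfo(names(chromLengths),
                                    as.integer(chromLengths)))
  names(gr) <- loci$gene_id
  mcols(gr)$ordinal <- as.integer(ord)
  new("GeneMap", taxon = as.character(taxon), loci = gr)
}

#' GainLossMap: reconstructed ancestral states and per-branch gene changes
#'
#' Result of [wagnerParsimony()] or [dolloParsimony()]: reconstructed
#' presence (or copy-number) states for every tree node and per-branch counts
#' of cluster gains and losses, together with per-cluster parsimony cost.
#'
#' @slot mode `"presence"`, `"count"` or `"dollo"`.
#' @slot states integer matrix, nodes x clusters; rownames are node labels.
#' @slot branches data.frame with columns `parent`, `child`, `length_mya`,
#'   `gains`, `losses`, `gene_gains`, `gene_losses`.
#' @slot clusterCost named numeric vector of per-cluster minimal change cost.
#' @export
setClass("GainLossMap",
         representation(mode = "character", states = "matrix",
                        branches = "data.frame", clusterCost = "numeric"))
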