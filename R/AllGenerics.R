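#' Accessors for package classes
#'
#' `taxonIds()` returns the taxa of a `ClusterTable` (or the single taxon of
#' a `Proteome`/`GeneMap`); `clusterIds()` the cluster identifiers;
#' `clusterCounts()` the clusters x taxa count matrix; `clusterMembers()` the
#' per-cluster membership list; `nProteins()` the number of proteins;
#' `sequences()` the underlying `AAStringSet`; `geneLoci()` the `GRanges` of
#' gene loci; `geneOrdinals()` the named ordinal vector.
#'
#' @param x an object of the corresponding class.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("taxonIds", function(x) standardGeneric("taxonIds"))
#' @rdname accessors
#' @export
setGeneric("clusterIds", function(x) standardGeneric("clusterIds"))
#' @rdname accessors
#' @export
setGeneric("clusterCounts", function(x) standardGeneric("clusterCounts"))
#' @rdname accessors
#' @export
setGeneric("clusterMembers", function(x) standardGeneric("clusterMembers"))
#' @rdname accessors
#' @export
setGeneric("nProteins", function(x) standardGeneric("nProteins"))
#' @rdname accessors
#' @export
setGeneric("sequences", function(x) standardGeneric("sequences"))
#' @rdname accessors
#' @export
setGeneric("geneLoci", function(x) standardGeneric("geneLoci"))
#' @rdname accessors
#' @export
setGeneric("geneOrdinals", function(x) standardGeneric("geneOrdinals"))

#' @rdname accessors
#' @export
setMethod("taxonIds", "Proteome", function(x) x@taxon)
#' @rdname accessors
#' @export
setMethod("taxonIds", "ClusterTable", function(x) colnames(x@counts))
#' @rdname accessors
#' @export
setMethod("taxonIds", "GeneMap", function(x) x@taxon)
#' @rdname accessors
#' @export
setMethod("taxonIds", "CladePartition", function(x) names(x@clades))

#' @rdname accessors
#' @export
setMethod("clusterIds", "ClusterTable", function(x) rownames(x@counts))
#' @rdname accessors
#' @export
setMethod("clusterCounts", "ClusterTable", function(x) x@counts)
#' @rdname accessors
#' @export
setMethod("clusterMembers", "ClusterTable", function(x) x@members)

#' @rdname accessors
#' @export
setMethod("nProteins", "Proteome", function(x) length(x@aa))
#' @rdname accessors
#' @export
setMethod("sequences", "Proteome", function(x) x@aa)

#' @rdname accessors
#' @export
setMethod("geneLoci", "GeneMap", function(x) x@loci)
#' @rdname accessors
#' @export
setMethod("geneOrdinals", "GeneMap", function(x)
  stats::setNames(S4Vectors::mcols(x@loci)$ordinal, names(x@loci)))

#' Clade utilities
#'
#' `cladeOf()` returns the clade label of each taxon; `ingroupTaxa()` and
#' `outgroupTaxa()` the ingroup/outgroup taxon sets; `speciesOf()` the
#' species of each taxon; `cladeTaxa()` the taxa of one clade.
#'
#' @param x a [CladePartition-class].
#' @param taxa taxon ids (default all).
#' @param clade a clade label.
#' @name clade-accessors
NULL

#' @rdname clade-accessors
#' @export
cladeOf <- function(x, taxa = taxonIds(x)) x@clades[taxa]
#' @rdname clade-accessors
#' @export
ingroupTaxa <- function(x) x@ingroup
#' @rdname clade-accessors
#' @export
outgroupTaxa <- function(x) setdiff(names(x@clades), x@ingroup)
#' @rdname clade-accessors
#' @export
speciesOf <- function(x, taxa = taxonIds(x)) x@species[taxa]
#' @rdname clade-accessors
#' @export
cladeTaxa <- function(x, clade) names(x@clades)[x@clades == clade]
#' @rdname clade-accessors
#' @export
cladeLabels <- function(x) setdiff(unique(unname(x@clades[x@ingroup])), "OUTGROUP")

setMethod("show", "Proteome", function(object) {
  cat("Proteome of", object@taxon, "with", length(object@aa), "proteins\n")
})

setMethod("show", "ClusterTable", function(object) {
  cat("ClusterTable:", nrow(object@counts), "clusters x",
      ncol(object@counts), "taxa;",
      if (length(object@members)) "with" else "without", "member lists\n")
})

setMethod("show", "CladePartition", function(object) {
  cl <- table(object@clades)
  cat("CladePartition:", length(object@ingroup), "ingroup taxa,",
      length(outgroupTaxa(object)), "outgroup;",
      paste(names(cl), as.integer(cl), sep = "=", collapse = ", "), "\n")
})

setMethod("show", "GeneMap", function(object) {
  cat("GeneMap of", object@taxon, "with", length(object@loci), "genes on",
      length(GenomeInfoDb::seqlevelsInUse(object@loci)), "chromosomes\n")
})

setMethod("show", "GainLossMap", function(object) {
  cat("GainLossMap (", object@mode, " mode): ", ncol(object@states),
      " clusters, ", nrow(object@branches), " branches, total cost ",
      sum(object@clusterCost), "\n", sep = "")
})

#' @rdname accessors
#' @export
branchChanges <- function(x) x@branches
#' @rdname accessors
#' @export
nodeStates <- function(x) x@states
#' @rdname accessors
#' @export
clusterCost <- function(x) x@clusterCost
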