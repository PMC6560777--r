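#' Species-level presence matrix
#'
#' Collapses strain columns of the same species by logical OR of presence
#' (a species "has" a cluster if any of its sequenced strains does).
#'
#' @param table a [ClusterTable-class].
#' @param partition a [CladePartition-class] supplying the taxon -> species
#'   map, or NULL to treat each taxon as its own species.
#' @param taxa restrict to these taxa first (default all).
#' @return logical matrix, clusters x species.
#' @export
speciesPresence <- function(table, partition = NULL, taxa = taxonIds(table)) {
  cts <- clusterCounts(table)[, taxa, drop = FALSE]
  pres <- cts >= 1L
  if (is.null(partition)) return(pres)
  sp <- speciesOf(partition, taxa)
  if (any(is.na(sp)))
    stop("taxa without species assignment: ",
         paste(taxa[is.na(sp)], collapse = ", "))
  grp <- split(seq_along(taxa), sp)
  out <- vapply(grp, function(i)
    rowSums(pres[, i, drop = FALSE]) > 0L, logical(nrow(pres)))
  if (nrow(pres) == 1L) out <- matrix(out, nrow = 1L,
                                      dimnames = list(rownames(pres),
                                                      names(grp)))
  out
}

#' Core genome: clusters present in every ingroup species
#'
#' Strains of one species are collapsed by OR before the test, so a
#' 13-strain, 12-species ingroup requires presence in each of the 12
#' species, not each strain.
#'
#' @param table a [ClusterTable-class].
#' @param partition a [CladePartition-class]; its ingroup defines the test
#'   set. Alternatively pass a plain character vector of ingroup taxa.
#' @return character vector of core cluster ids.
#' @export
coreClusters <- function(table, partition) {
  if (is.character(partition)) {
    taxa <- partition; part <- NULL
  } else {
    taxa <- ingroupTaxa(partition); part <- partition
  }
  if (!length(taxa)) stop("empty ingroup")
  missing <- setdiff(taxa, taxonIds(table))
  if (length(missing))
    stop("ingroup taxa absent from table: ", paste(missing, collapse = ", "))
  pres <- speciesPresence(table, part, taxa)
  rownames(pres)[rowSums(pres) == ncol(pres)]
}

#' Single-copy ortholog clusters
#'
#' Clusters with exactly one gene in (almost) every ingroup taxon: counts in
#' \{0, 1\} for all ingroup taxa, no taxon with more than one copy, and at
#' most `allowMissing` taxa at zero.
#'
#' @param table a [ClusterTable-class].
#' @param ingroup taxa to test (character vector or [CladePartition-class]).
#' @param allowMissing maximum number of absent taxa (default 1).
#' @return character vector of cluster ids.
#' @export
singleCopyOrthologs <- function(table, ingroup, allowMissing = 1L) {
  if (is(ingroup, "CladePartition")) ingroup <- ingroupTaxa(ingroup)
  stopifnot(allowMissing >= 0L)
  cts <- clusterCounts(table)[, ingroup, drop = FALSE]
  ok <- rowSums(cts > 1L) == 0L &
    rowSums(cts == 1L) >= length(ingroup) - allowMissing
  rownames(cts)[ok]
}

#' Subset-specific clusters (all-but-one rule)
#'
#' Clusters present in at least `|subset| - 1` of the subset taxa and in no
#' taxon outside the subset.
#'
#' @param table a [ClusterTable-class].
#' @param subset non-empty proper subset of the table's taxa.
#' @return character vector of cluster ids.
#' @export
subsetSpecific <- function(table, subset) {
  taxa <- taxonIds(table)
  if (!length(subset)) stop("empty subset")
  if (!all(subset %in% taxa))
    stop("unknown taxa in subset: ",
         paste(setdiff(subset, taxa), collapse = ", "))
  outside <- setdiff(taxa, subset)
  if (!length(outside)) stop("subset equals the full taxon set (no outside)")
  pres <- clusterCounts(table) >= 1L
  inN <- rowSums(pres[, subset, drop = FALSE])
  outN <- rowSums(pres[, outside, drop = FALSE])
  rownames(pres)[inN >= length(subset) - 1L & outN == 0L]
}

#' Classify clusters by clade distribution and summarize per species
#'
#' Assigns each cluster one category with fixed precedence
#' `genus_wide > multi_clade > clade_only > species_only`:
#' \itemize{
#'   \item `genus_wide`: present in every ingroup species;
#'   \item `multi_clade`: present in two or more ingroup clades;
#'   \item `clade_only(<label>)`: presence confined to one clade, at least
#'     two of its species;
#'   \item `species_only(<species>)`: exactly one ingroup species;
#'   \item `outgroup_shared`: no ingroup member at all.
#' }
#' The per-species summary mirrors a clade-distribution table: clusters
#' present in the species; of those, clusters with at least two species from
#' each ingroup clade (`requireAllClades = TRUE`, the default) or from each
#' clade represented in the cluster (`FALSE`); clusters confined to the
#' species' own clade; clusters (with any ingroup member) the species lacks;
#' and the species' total gene count.
#'
#' @param table a [ClusterTable-class].
#' @param partition a [CladePartition-class] covering all ingroup taxa.
#' @param requireAllClades see above.
#' @return list with `categories` (data.frame: cluster_id, category, clade)
#'   and `summary` (data.frame per species).
#' @export
classifyByClade <- function(table, partition, requireAllClades = TRUE) {
  ing <- ingroupTaxa(partition)
  missing <- setdiff(ing, taxonIds(table))
  if (length(missing))
    stop("ingroup taxa absent from table: ", paste(missing, collapse = ", "))
  noclade <- ing[is.na(cladeOf(partition, ing))]
  if (length(noclade))
    stop("taxon without clade label: ", paste(noclade, collapse = ", "))
  spPres <- speciesPresence(table, partition, ing)       # clusters x species
  spOf <- vapply(split(cladeOf(partition, ing),
                       speciesOf(partition, ing)), function(x)
                         unique(x)[1L], "")
  spOf <- spOf[colnames(spPres)]
  clades <- sort(unique(spOf))
  nSpecies <- ncol(spPres)
  # species-per-clade counts per cluster
  perClade <- vapply(clades, function(cl)
    rowSums(spPres[, spOf == cl, drop = FALSE]), numeric(nrow(spPres)))
  if (nrow(spPres) == 1L)
    perClade <- matrix(perClade, nrow = 1L,
                       dimnames = list(rownames(spPres), clades))
  nIng <- rowSums(spPres)
  nClades <- rowSums(perClade >= 1L)
  category <- rep("other", nrow(spPres))
  cladeLab <- rep(NA_character_, nrow(spPres))
  category[nIng == 0L] <- "outgroup_shared"
  one <- nClades == 1L
  onlyClade <- rep(NA_character_, nrow(spPres))
  onlyClade[one] <- clades[apply(perClade[one, , drop = FALSE] >= 1L, 1L,
                                 which.max)]
  sel <- nIng == 1L
  category[sel] <- "species_only"
  cladeLab[sel] <- onlyClade[sel]
  sel <- one & nIng >= 2L
  category[sel] <- "clade_only"
  cladeLab[sel] <- onlyClade[sel]
  sel <- nClades >= 2L
  category[sel] <- "multi_clade"
  sel <- nIng == nSpecies
  category[sel] <- "genus_wide"
  cladeLab[sel] <- NA
  categories <- data.frame(cluster_id = rownames(spPres),
                           category = category, clade = cladeLab,
                           stringsAsFactors = FALSE)
  # per-species summary
  twoEach <- if (requireAllClades) {
    rowSums(perClade >= 2L) == length(clades)
  } else {
    rowSums(perClade >= 2L) == nClades & nClades >= 1L
  }
  anyIng <- nIng >= 1L
  cts <- clusterCounts(table)
  sumRows <- lapply(colnames(spPres), function(sp) {
    has <- spPres[, sp]
    strains <- ing[speciesOf(partition, ing) == sp]
    data.frame(species = sp, clade = spOf[[sp]],
               present_in = sum(has),
               two_per_clade = sum(has & twoEach),
               clade_only = sum(has & category == "clade_only" &
                                  cladeLab == spOf[[sp]]),
               absent_from = sum(anyIng & !has),
               total_genes = sum(cts[, strains]),
               stringsAsFactors = FALSE)
  })
  list(categories = categories, summary = do.call(rbind, sumRows))
}

#' Cluster counts for every combination of taxon groups (UpSet-style)
#'
#' For each of the `2^g - 1` non-empty combinations of the named groups,
#' counts clusters present in at least one taxon of every included group and
#' in no taxon of any excluded group. The counts sum to the number of
#' clusters present in at least one group.
#'
#' @param table a [ClusterTable-class].
#' @param groups named list of taxon vectors (groups may share taxa);
#'   at most 12 groups.
#' @return data.frame with columns `combination` (group names joined by
#'   `"&"`), `degree` and `count`.
#' @export
intersectionCounts <- function(table, groups) {
  g <- length(groups)
  if (g < 1L) stop("need at least one group")
  if (g > 12L) stop("more than 12 groups (combinatorial guard)")
  if (is.null(names(groups)) || any(!nzchar(names(groups))))
    stop("groups must be named")
  pres <- clusterCounts(table) >= 1L
  inGroup <- vapply(groups, function(tx)
    rowSums(pres[, intersect(tx, colnames(pres)), drop = FALSE]) > 0L,
    logical(nrow(pres)))
  if (nrow(pres) == 1L)
    inGroup <- matrix(inGroup, nrow = 1L, dimnames = list(rownames(pres),
                                                          names(groups)))
  combos <- expand.grid(rep(list(c(FALSE, TRUE)), g))
  combos <- combos[rowSums(combos) > 0L, , drop = FALSE]
  res <- apply(combos, 1L, function(incl) {
    sum(rowSums(inGroup[, incl, drop = FALSE]) == sum(incl) &
          rowSums(inGroup[, !incl, drop = FALSE]) == 0L)
  })
  data.frame(
    combination = apply(combos, 1L, function(incl)
      paste(names(groups)[as.logical(incl)], collapse = "&")),
    degree = rowSums(combos),
    count = as.integer(res),
    stringsAsFactors = FALSE, row.names = NULL)
}

#' Gene-level difference between two strains
#'
#' Counts genes private to each strain (genes in clusters with no member
#' from the other strain) and shared genes, with percentages against each
#' strain's total gene count. Totals default to the strains' clustered gene
#' counts; pass `totalA`/`totalB` when unclustered genes are known (e.g.
#' annotated genome totals).
#'
#' @param table a [ClusterTable-class].
#' @param taxonA,taxonB the two strains.
#' @param totalA,totalB total gene counts for percentage denominators.
#' @return data.frame with one row: `n_a_only`, `n_b_only`, `n_shared_a`,
#'   `n_shared_b`, `pct_a_only`, `pct_b_only` (integer-rounded percent).
#' @export
strainDifference <- function(table, taxonA, taxonB,
                             totalA = NULL, totalB = NULL) {
  cts <- clusterCounts(table)
  for (t in c(taxonA, taxonB))
    if (!t %in% colnames(cts)) stop("unknown taxon: ", t)
  a <- cts[, taxonA]; b <- cts[, taxonB]
  nAonly <- sum(a[b == 0L]); nBonly <- sum(b[a == 0L])
  shA <- sum(a[b > 0L]); shB <- sum(b[a > 0L])
  if (is.null(totalA)) totalA <- sum(a)
  if (is.null(totalB)) totalB <- sum(b)
  data.frame(n_a_only = nAonly, n_b_only = nBonly,
             n_shared_a = shA, n_shared_b = shB,
             pct_a_only = round(100 * nAonly / totalA),
             pct_b_only = round(100 * nBonly / totalB))
}

#' Screen species by sequence-database abundance
#'
#' Ranks species by the number of deposited sequences, reports each species'
#' integer-rounded share of the total, and classifies species as `rare`
#' (fewer than `rareBelow` sequences), `common` (more than `commonAbove`) or
#' `intermediate`.
#'
#' @param records data.frame with columns `species` and `n` (non-negative
#'   sequence counts).
#' @param rareBelow,commonAbove class thresholds (defaults 50 and 100).
#' @return data.frame ranked by `n` descending with columns `species`, `n`,
#'   `share_pct`, `class`; attributes `class_pct` (named integer-rounded
#'   percentages of species per class) and `total`.
#' @export
screenSpeciesAbundance <- function(records, rareBelow = 50,
                                   commonAbove = 100) {
  stopifnot(all(c("species", "n") %in% names(records)))
  if (any(records$n < 0)) stop("negative sequence count")
  total <- sum(records$n)
  if (total == 0) stop("total sequence count is zero")
  out <- records[order(-records$n), c("species", "n")]
  out$share_pct <- round(100 * out$n / total)
  out$class <- ifelse(out$n < rareBelow, "rare",
                      ifelse(out$n > commonAbove, "common", "intermediate"))
  cls <- table(factor(out$class, levels = c("rare", "intermediate",
                                            "common")))
  attr(out, "class_pct") <- round(100 * as.integer(cls) / nrow(out)) |>
    stats::setNames(names(cls))
  attr(out, "total") <- total
  rownames(out) <- NULL
  out
}
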