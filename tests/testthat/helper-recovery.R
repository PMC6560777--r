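# Truth-derived expectations for pipeline-recovery checks. Protein ids in
# the simulator equal family ids, so a recovered cluster maps to a family
# via its (unique) member protein id; impurity breaks the mapping and any
# set comparison built on it.

speciesORPresence <- function(presence, partition) {
  taxa <- colnames(presence)
  sp <- speciesOf(partition, taxa)
  sp[is.na(sp)] <- taxa[is.na(sp)]
  grp <- split(seq_along(taxa), sp)
  out <- vapply(grp, function(i)
    rowSums(presence[, i, drop = FALSE]) > 0, logical(nrow(presence)))
  out
}

expectedFamilySets <- function(truth, partition) {
  pres <- truth$presence
  ing <- intersect(ingroupTaxa(partition), colnames(pres))
  og <- intersect(outgroupTaxa(partition), colnames(pres))
  spPres <- speciesORPresence(pres, partition)
  ingSp <- unique(speciesOf(partition, ing))
  core <- rownames(pres)[rowSums(spPres[, ingSp, drop = FALSE]) ==
                           length(ingSp)]
  genus <- core[rowSums(pres[core, og, drop = FALSE]) == 0]
  clades <- list()
  for (cl in cladeLabels(partition)) {
    tx <- intersect(cladeTaxa(partition, cl), colnames(pres))
    outside <- setdiff(colnames(pres), tx)
    clades[[cl]] <- rownames(pres)[
      rowSums(pres[, tx, drop = FALSE] >= 1) >= length(tx) - 1 &
        rowSums(pres[, outside, drop = FALSE] >= 1) == 0]
  }
  speciesOnly <- list()
  for (tx in ing) {
    fams <- rownames(pres)[pres[, tx] == 1 &
                             rowSums(pres) == 1]
    if (!is.null(truth$sscpTaxon) && identical(tx, truth$sscpTaxon))
      fams <- c(fams, names(truth$sscp))
    speciesOnly[[tx]] <- fams
  }
  list(core = core, genus = genus, clades = clades,
       speciesOnly = speciesOnly)
}

# recovered cluster ids -> family ids (NA when a cluster mixes families)
clusterToFamily <- function(table) {
  vapply(clusterMembers(table), function(m) {
    u <- unique(m$protein)
    if (length(u) == 1L) u else NA_character_
  }, "")
}
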