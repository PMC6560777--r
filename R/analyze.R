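# tiny stable content hash (FNV-1a, 32 bit) for the run manifest
fnv1a <- function(x) {
  bytes <- utf8ToInt(x)
  h <- 21661362
  for (b in bytes) {
    h <- bitwXor(as.integer(h), as.integer(b))
    h <- (h * 16777619) %% 2147483629   # stay inside R's integer range
  }
  sprintf("%08x", as.integer(h))
}

#' Run the full comparative analysis and write a report directory
#'
#' Chains the package end to end: simulate (or ingest) inputs, cluster
#' proteomes by reciprocal best hits (unless a precomputed cluster table is
#' supplied), then compute the pan-genome partition, clade classification,
#' intersection counts, orphan sets, orphan chromosome geometry, the SSCP
#' census and the Wagner gain/loss reconstruction with per-Mya rates.
#' Writes one TSV per result plus `manifest.json` (package version, config
#' hash, per-stage row counts). Deterministic for a fixed config and seed.
#'
#' @param outDir output directory (created; existing files overwritten).
#' @param config a [simConfig()] when `simulate = TRUE`; otherwise a list
#'   with paths: `groups` or `proteomeDir`, `clades`, `tree`, optional
#'   `genemap`, optional `secretionCalls`, plus thresholds `minScore`,
#'   `windowBp`, `maxLen`, `minCysFrac`.
#' @param simulate generate inputs with [simulateStudy()] (default TRUE).
#' @param minScore RBH similarity threshold.
#' @param windowBp subtelomere window.
#' @param maxLen,minCysFrac SSCP filter parameters.
#' @return (invisibly) a list with every computed object and `manifest`.
#' @export
runAnalysis <- function(outDir, config = simConfig(), simulate = TRUE,
                        minScore = 0.5, windowBp = 1e5, maxLen = 300L,
                        minCysFrac = 0.05) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  if (simulate) {
    study <- simulateStudy(config)
    proteomes <- study$proteomes
    tree <- study$tree
    partition <- study$partition
    genemap <- study$genemap
    orphanGeneIds <- study$truth$genemap$orphanIds
    table <- clusterProteomes(proteomes, minScore = minScore)
    secretionCalls <- NULL
  } else {
    if (!is.null(config$clades) && !file.exists(config$clades))
      stop("missing clade file: ", config$clades, call. = FALSE)
    partition <- readCladePartition(config$clades)
    tree <- readNewick(config$tree)
    proteomes <- NULL
    if (!is.null(config$proteomeDir)) {
      files <- list.files(config$proteomeDir, pattern = "\\.fa(a|sta)?$",
                          full.names = TRUE)
      proteomes <- lapply(files, readProteome)
      names(proteomes) <- vapply(proteomes, taxonIds, "")
    }
    table <- if (!is.null(config$groups)) readGroups(config$groups) else
      clusterProteomes(proteomes, minScore = minScore)
    genemap <- if (!is.null(config$genemap)) readGeneMap(config$genemap)
      else NULL
    orphanGeneIds <- NULL
    secretionCalls <- if (!is.null(config$secretionCalls))
      readSecretionCalls(config$secretionCalls) else NULL
  }
  res <- list()
  wr <- function(df, name) {
    utils::write.table(df, file.path(outDir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    nrow(df)
  }
  rows <- c()
  core <- coreClusters(table, partition)
  rows["core.tsv"] <- wr(data.frame(cluster_id = core), "core.tsv")
  cls <- classifyByClade(table, partition)
  rows["categories.tsv"] <- wr(cls$categories, "categories.tsv")
  rows["clade_summary.tsv"] <- wr(cls$summary, "clade_summary.tsv")
  groups <- lapply(cladeLabels(partition), function(cl)
    cladeTaxa(partition, cl))
  names(groups) <- cladeLabels(partition)
  ic <- intersectionCounts(table, groups)
  rows["intersections.tsv"] <- wr(ic, "intersections.tsv")
  orph <- findOrphans(table, partition, "genus")
  orphRows <- data.frame(level = "genus", clusters = orph$clusters,
                         stringsAsFactors = FALSE)
  for (cl in cladeLabels(partition)) {
    oc <- findOrphans(table, partition, "clade", clade = cl)
    if (length(oc$clusters))
      orphRows <- rbind(orphRows,
                        data.frame(level = paste0("clade_", cl),
                                   clusters = oc$clusters))
  }
  rows["orphans.tsv"] <- wr(orphRows, "orphans.tsv")
  if (!is.null(genemap)) {
    ids <- if (!is.null(orphanGeneIds)) orphanGeneIds else
      intersect(unlist(orph$genes), names(geneLoci(genemap)))
    runs <- orphanRuns(genemap, ids)
    rows["orphan_runs.tsv"] <- wr(runs$clusters, "orphan_runs.tsv")
    st <- subtelomericFraction(genemap, ids, windowBp = windowBp)
    rows["subtelomeric.tsv"] <- wr(st$perGene, "subtelomeric.tsv")
    res$subtelomeric <- st
    res$orphanRuns <- runs
  }
  if (!is.null(proteomes)) {
    cen <- sscpCensus(proteomes, maxLen = maxLen, minCysFrac = minCysFrac,
                      secretionCalls = secretionCalls)
    rows["sscp_census.tsv"] <- wr(cen$census, "sscp_census.tsv")
    res$sscp <- cen
  }
  gl <- wagnerParsimony(table, tree, mode = "presence",
                        partition = partition)
  br <- branchRates(gl)
  rows["branches.tsv"] <- wr(br, "branches.tsv")
  manifest <- list(
    package = "PanGenEvo",
    version = as.character(utils::packageVersion("PanGenEvo")),
    config_hash = fnv1a(jsonlite::toJSON(
      if (simulate) list(seed = config$seed, simulate = TRUE) else config,
      auto_unbox = TRUE, force = TRUE)),
    simulate = simulate,
    n_clusters = nrow(clusterCounts(table)),
    n_taxa = ncol(clusterCounts(table)),
    rows = as.list(rows))
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  res <- c(res, list(table = table, core = core, categories = cls,
                     intersections = ic, orphans = orph, gainloss = gl,
                     branches = br, manifest = manifest,
                     partition = partition, tree = tree))
  invisible(res)
}
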