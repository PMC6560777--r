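test_that("no events means every root family survives everywhere", {
  cfg <- simConfig(gainRate = 0, lossRate = 0, nRootFamilies = 50,
                   nPlanted = c(core = 0), partition = NULL, seed = 2)
  fam <- simulateFamilyEvolution(cfg)
  cts <- clusterCounts(fam$table)
  expect_equal(nrow(cts), 50L)
  expect_true(all(cts == 1L))
  expect_true(all(fam$truth$branchGains == 0L))
  expect_true(all(fam$truth$branchLosses == 0L))
})

test_that("saturating loss removes all root families from the leaves", {
  cfg <- simConfig(gainRate = 0, lossRate = 1e3, nRootFamilies = 50,
                   nPlanted = c(core = 0), partition = NULL, seed = 3)
  fam <- simulateFamilyEvolution(cfg)
  expect_true(all(clusterCounts(fam$table) == 0L))
})

test_that("leaf family counts match the analytic survival expectation", {
  # with gains off, P(root family present at leaf) = exp(-loss * depth)
  tr <- validateTimeTree(ape::read.tree(
    text = "(((A:2,B:2):3,C:5):5,((D:4,E:4):2,F:6):4);"))
  loss <- 0.2
  depth <- ape::node.depth.edgelength(tr)[1:6]
  names(depth) <- tr$tip.label
  expected <- 40 * exp(-loss * depth)
  tally <- setNames(numeric(6), tr$tip.label)
  nrep <- 300
  for (i in seq_len(nrep)) {
    cfg <- simConfig(tree = tr, partition = NULL, gainRate = 0,
                     lossRate = loss, nRootFamilies = 40,
                     nPlanted = c(core = 0), seed = 5000 + i)
    cts <- clusterCounts(simulateFamilyEvolution(cfg)$table)
    tally <- tally + colSums(cts)[tr$tip.label]
  }
  observed <- tally / nrep
  # Monte-Carlo tolerance: 4 sigma of a binomial mean over 300 x 40 draws
  sigma <- sqrt(expected / 40 * (1 - expected / 40) * 40 / nrep)
  expect_true(all(abs(observed - expected) < 4 * sigma + 0.5))
})

test_that("planted categories satisfy their defining presence patterns", {
  cfg <- simConfig(seed = 13)
  fam <- simulateFamilyEvolution(cfg)
  part <- cfg$partition
  pres <- fam$truth$presence
  cat_ <- fam$truth$category
  ing <- ingroupTaxa(part); og <- outgroupTaxa(part)
  core <- names(cat_)[cat_ == "core"]
  expect_true(all(pres[core, ] == 1L))
  gor <- names(cat_)[cat_ == "genus_orphan"]
  expect_true(all(pres[gor, ing] == 1L))
  expect_true(all(pres[gor, og] == 0L))
  for (cl in cladeLabels(part)) {
    ids <- names(cat_)[cat_ == paste0("clade_", cl)]
    tx <- cladeTaxa(part, cl)
    expect_true(all(pres[ids, tx] == 1L))
    expect_true(all(pres[ids, setdiff(colnames(pres), tx)] == 0L))
  }
  sor <- names(cat_)[startsWith(cat_, "species_orphan")]
  expect_true(all(rowSums(pres[sor, , drop = FALSE]) == 1L))
})

test_that("simulation output is deterministic for a fixed seed", {
  s1 <- simulateStudy(simConfig(seed = 9, nRootFamilies = 20))
  s2 <- simulateStudy(simConfig(seed = 9, nRootFamilies = 20))
  expect_identical(clusterCounts(s1$table), clusterCounts(s2$table))
  expect_identical(lapply(s1$proteomes, function(p)
    as.character(sequences(p))),
    lapply(s2$proteomes, function(p) as.character(sequences(p))))
  d1 <- tempfile(); d2 <- tempfile()
  writeSimulation(s1, d1); writeSimulation(s2, d2)
  for (f in list.files(d1, recursive = TRUE))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  s3 <- simulateStudy(simConfig(seed = 10, nRootFamilies = 20))
  expect_false(identical(clusterCounts(s1$table), clusterCounts(s3$table)))
})

test_that("zero divergence emits identical family members", {
  cfg <- simConfig(divergenceScale = 0, seed = 4, nRootFamilies = 10,
                   nPlanted = c(core = 2))
  st <- simulateStudy(cfg, plantSscp = FALSE, makeGeneMap = FALSE)
  pres <- st$truth$presence
  for (f in rownames(pres)[rowSums(pres) >= 2]) {
    tx <- colnames(pres)[pres[f, ] == 1L]
    seqs <- vapply(tx, function(t)
      as.character(sequences(st$proteomes[[t]])[[f]]), "")
    expect_equal(length(unique(seqs)), 1L)
  }
})

test_that("orphan families show no cross-family similarity to outgroups", {
  cfg <- simConfig(seed = 21)
  st <- simulateStudy(cfg, plantSscp = FALSE, makeGeneMap = FALSE)
  cat_ <- st$truth$category
  gor <- names(cat_)[cat_ == "genus_orphan"]
  ingTx <- ingroupTaxa(cfg$partition)[1]
  outTx <- outgroupTaxa(cfg$partition)[1]
  oseqs <- as.character(sequences(st$proteomes[[outTx]]))
  n <- 0; below <- 0
  for (f in gor) {
    s <- as.character(sequences(st$proteomes[[ingTx]])[[f]])
    for (o in oseqs[seq_len(min(10, length(oseqs)))]) {
      n <- n + 1
      if (pairwiseSimilarity(s, o) < 0.5) below <- below + 1
    }
  }
  expect_gte(below / n, 0.99)
})

test_that("planted gene-map layouts are recovered exactly", {
  gm <- emitGeneMap("T", layout = list(nSingletons = 0,
                                       clusterSizes = c("8" = 1),
                                       subtelomericFraction = 0),
                    seed = 6)
  r <- orphanRuns(gm$genemap, gm$truth$orphanIds)
  expect_equal(r$clusters$size, 8L)
  ords <- sort(geneOrdinals(gm$genemap)[gm$truth$orphanIds])
  expect_equal(unname(diff(ords)), rep(1L, 7))     # consecutive ordinals
  expect_equal(subtelomericFraction(gm$genemap,
                                    gm$truth$orphanIds)$fraction, 0)
  expect_equal(gm$truth$nSubtelomeric, 0L)
})

test_that("infeasible layouts are rejected", {
  expect_error(emitGeneMap("T", layout = list(
    chromLengths = c(chr1 = 2e4), nSingletons = 50,
    clusterSizes = c("2" = 5)), seed = 1), "infeasible")
})

test_that("codon pair simulation respects t = 0 limit and validity", {
  expect_error(simulateCodonPair(0, 1), "omega")
  cp <- simulateCodonPair(1, 1e-9, nCodons = 50, seed = 2)
  r <- ng86dNdS(cp)
  expect_equal(r$dN, 0); expect_equal(r$dS, 0)
  cp2 <- simulateCodonPair(0.5, 0.6, nCodons = 200, seed = 3)
  # no stop codons anywhere
  for (s in c(cp2$a, cp2$b)) {
    cods <- substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))
    expect_false(any(cods %in% c("TAA", "TAG", "TGA")))
  }
})
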