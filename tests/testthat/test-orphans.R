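test_that("orphan detection at genus, clade and species level", {
  m <- rbind(G1 = c(A = 1, B = 1, C = 1, O = 0),   # genus orphan
             G2 = c(A = 1, B = 1, C = 1, O = 1),   # core but shared outside
             P1 = c(A = 1, B = 1, C = 0, O = 0),   # clade P specific
             S1 = c(A = 0, B = 0, C = 2, O = 0),   # species-private
             X1 = c(A = 1, B = 0, C = 0, O = 1))   # shared with outgroup
  tab <- ClusterTable(counts = m)
  part <- CladePartition(c(A = "P", B = "P", C = "Q", O = "OUTGROUP"))
  expect_setequal(findOrphans(tab, part, "genus")$clusters, "G1")
  expect_setequal(findOrphans(tab, part, "species", taxon = "C")$clusters,
                  "S1")
  expect_error(findOrphans(tab, part, "protein"), "arg")
})

test_that("clade orphans exclude clusters leaking outside the clade", {
  m <- rbind(P1 = c(A = 1, B = 1, C = 0, O = 0),
             P2 = c(A = 1, B = 0, C = 0, O = 0),
             P3 = c(A = 1, B = 1, C = 1, O = 0),
             P4 = c(A = 1, B = 1, C = 0, O = 1))
  tab <- ClusterTable(counts = m)
  part <- CladePartition(c(A = "P", B = "P", C = "Q", O = "OUTGROUP"))
  got <- findOrphans(tab, part, "clade", clade = "P")$clusters
  expect_setequal(got, c("P1", "P2"))   # P3 leaks to Q, P4 to outgroup
  sp <- findOrphans(tab, part, "species", taxon = "C")$clusters
  expect_length(sp, 0L)
  expect_error(findOrphans(tab, part, "species"), "taxon")
})

test_that("genus orphans are a subset of the core genome", {
  set.seed(41)
  taxa <- c("A", "B", "C", "O1", "O2")
  part <- CladePartition(c(A = "P", B = "P", C = "Q", O1 = "OUTGROUP",
                           O2 = "OUTGROUP"))
  for (rep in 1:30) {
    tab <- randomPresenceTable(25, taxa, pPresent = 0.6)
    orph <- findOrphans(tab, part, "genus")$clusters
    core <- coreClusters(tab, part)
    expect_true(all(orph %in% core))
  }
})

test_that("orphan runs follow strict chromosomal adjacency", {
  loci <- data.frame(gene_id = sprintf("g%d", 1:10), chrom = "chr1",
                     start = (0:9) * 1000 + 1, end = (0:9) * 1000 + 900)
  gm <- GeneMap("T", loci, c(chr1 = 2e5))
  r <- orphanRuns(gm, c("g4", "g5", "g6"))
  expect_equal(r$clusters$size, 3L)
  expect_equal(r$clusters$first_ordinal, 4L)
  expect_length(r$singletons, 0L)

  r2 <- orphanRuns(gm, c("g4", "g6"))          # non-orphan g5 between
  expect_equal(nrow(r2$clusters), 0L)
  expect_setequal(r2$singletons, c("g4", "g6"))

  r3 <- orphanRuns(gm, c("g4", "g6"), maxGap = 1L)  # tolerant reading
  expect_equal(r3$clusters$size, 2L)

  expect_warning(r4 <- orphanRuns(gm, c("g4", "nope")), "nope")
  expect_identical(r4$missing, "nope")
  expect_setequal(r4$singletons, "g4")
})

test_that("run conservation: singletons + clustered = mapped orphans", {
  set.seed(43)
  for (rep in 1:20) {
    gm <- emitGeneMap("T", seed = rep)
    truth <- gm$truth
    r <- orphanRuns(gm$genemap, truth$orphanIds)
    expect_equal(length(r$singletons) + sum(r$clusters$size),
                 length(truth$orphanIds))
  }
})

test_that("subtelomeric classification uses the midpoint rule", {
  loci <- data.frame(gene_id = c("near", "mid", "far"), chrom = "chr1",
                     start = c(99000, 499500, 4900000),
                     end = c(101000, 500500, 4999000))
  gm <- GeneMap("T", loci, c(chr1 = 5e6))
  res <- subtelomericFraction(gm, windowBp = 1e5)
  cls <- setNames(res$perGene$class, res$perGene$gene_id)
  expect_identical(unname(cls["near"]), "subtelomeric")  # midpoint 1e5
  expect_identical(unname(cls["mid"]), "middle")
  expect_identical(unname(cls["far"]), "subtelomeric")   # near far end
  expect_equal(res$fraction, 2 / 3)

  # midpoint exactly at length/2 of a 1 Mb chromosome is middle
  gm2 <- GeneMap("T", data.frame(gene_id = "c", chrom = "chr1",
                                 start = 499501, end = 500500),
                 c(chr1 = 1e6))
  expect_identical(subtelomericFraction(gm2, windowBp = 1e5)$perGene$class,
                   "middle")
  expect_error(subtelomericFraction(gm, "nope"), "nope")
})

test_that("widening the window never lowers the subtelomeric fraction", {
  set.seed(47)
  gm <- emitGeneMap("T", seed = 3)$genemap
  fr <- vapply(c(0, 2e4, 5e4, 1e5, 3e5, 1e6), function(w)
    subtelomericFraction(gm, windowBp = w)$fraction, 0)
  expect_true(all(diff(fr) >= 0))
})
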