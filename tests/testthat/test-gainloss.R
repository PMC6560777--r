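balanced4 <- function() validateTimeTree(
  ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);"))

test_that("trivial reconstructions: ubiquitous and singleton clusters", {
  tr <- balanced4()
  m <- rbind(ALL = c(A = 1, B = 1, C = 1, D = 1),
             ONE = c(A = 1, B = 0, C = 0, D = 0))
  gl <- wagnerParsimony(ClusterTable(counts = m), tr)
  expect_equal(unname(clusterCost(gl)), c(0, 1))
  st <- nodeStates(gl)
  expect_true(all(st[, "ALL"] == 1L))       # present at every ancestor
  br <- branchChanges(gl)
  expect_equal(br$gains[br$child == "A"], 1L)  # gain on the terminal branch
  expect_true(all(st[c("N1", "N2"), "ONE"] == 0L))
  expect_equal(sum(br$gains + br$losses), 1L)
})

test_that("leaf mismatches are reported with the symmetric difference", {
  tr <- balanced4()
  m <- rbind(K = c(A = 1, B = 1, C = 1, E = 1))
  expect_error(wagnerParsimony(ClusterTable(counts = m), tr), "D.*E|E.*D")
})

test_that("presence-mode minimal cost equals exhaustive enumeration", {
  skip_if_not_installed("phangorn")
  set.seed(53)
  for (n in 3:5) {
    trees <- phangorn::allTrees(n, rooted = TRUE,
                                tip.label = LETTERS[1:n])
    idx <- unique(round(seq(1, length(trees),
                            length.out = min(8, length(trees)))))
    for (i in idx) {
      tr <- validateTimeTree(trees[[i]], requireLengths = FALSE)
      P <- matrix(rbinom(n * 50, 1, 0.5), nrow = n,
                  dimnames = list(tr$tip.label, sprintf("K%02d", 1:50)))
      tab <- ClusterTable(counts = t(P))
      gl <- wagnerParsimony(tab, tr)
      oracle <- bruteForceWagnerCost(tr, P[tr$tip.label, , drop = FALSE])
      expect_equal(unname(clusterCost(gl)), unname(oracle))
    }
  }
})

test_that("count mode uses linear Wagner costs and prefers smaller states", {
  tr <- balanced4()
  m <- rbind(K = c(A = 3, B = 3, C = 0, D = 0))
  gl <- wagnerParsimony(ClusterTable(counts = m), tr, mode = "count")
  expect_equal(unname(clusterCost(gl)), 3)
  st <- nodeStates(gl)
  expect_equal(unname(st["N1", "K"]), 0L)  # root kept low by tie-break
  expect_equal(unname(st["N2", "K"]), 3L)  # (A,B) ancestor at 3
  br <- branchChanges(gl)
  expect_equal(sum(br$gene_gains), 3L)
  expect_equal(sum(br$gene_losses), 0L)
})

test_that("branch rates divide changes by branch length, never infinite", {
  tr <- validateTimeTree(ape::read.tree(text = "((A:5,B:5):0,C:5);"))
  m <- rbind(K1 = c(A = 1, B = 1, C = 0), K2 = c(A = 1, B = 0, C = 0))
  gl <- wagnerParsimony(ClusterTable(counts = m), tr)
  br <- branchRates(gl)
  expect_true(all(is.na(br$rate[br$length_mya == 0])))
  ab <- br[br$child == "A", ]
  expect_equal(ab$rate, (ab$gains + ab$losses) / 5)
  expect_true(all(br$rate[!is.na(br$rate)] >= 0))
})

test_that("Dollo places one gain at the MRCA and minimal losses", {
  tr <- balanced4()
  sis <- dolloParsimony(ClusterTable(
    counts = rbind(SIS = c(A = 1, B = 1, C = 0, D = 0))), tr)
  brS <- branchChanges(sis)
  expect_equal(brS$gains[brS$child == "N2"], 1L)  # gain on the (A,B) stem
  expect_equal(sum(brS$losses), 0L)
  expect_equal(unname(clusterCost(sis)["SIS"]), 1)
  # non-sisters: MRCA is the root; two losses, no branch gain
  far <- dolloParsimony(ClusterTable(
    counts = rbind(FAR = c(A = 1, B = 0, C = 1, D = 0))), tr)
  brF <- branchChanges(far)
  expect_equal(sum(brF$gains), 0L)
  expect_setequal(brF$child[brF$losses == 1L], c("B", "D"))
  expect_equal(unname(clusterCost(far)["FAR"]), 2)
  st <- nodeStates(far)
  expect_equal(unname(st["N1", "FAR"]), 1L)
  expect_equal(unname(st[c("B", "D"), "FAR"]), c(0L, 0L))
})

test_that("Dollo cost is never below the Wagner minimum", {
  set.seed(59)
  for (rep in 1:100) {
    n <- sample(4:8, 1)
    tr <- validateTimeTree(ape::rtree(n), requireLengths = FALSE)
    tab <- randomPresenceTable(10, tr$tip.label, pPresent = 0.5)
    w <- clusterCost(wagnerParsimony(tab, tr))
    d <- clusterCost(dolloParsimony(tab, tr))
    expect_true(all(d >= w - 1e-9))
    expect_true(all(w >= 0) && all(d >= 0))
  }
})

test_that("parsimony score is invariant under consistent relabeling", {
  set.seed(61)
  tr <- validateTimeTree(ape::rtree(6), requireLengths = FALSE)
  tab <- randomPresenceTable(20, tr$tip.label, pPresent = 0.5)
  sc1 <- sort(unname(clusterCost(wagnerParsimony(tab, tr))))
  relabel <- setNames(paste0("z", tr$tip.label), tr$tip.label)
  tr2 <- tr; tr2$tip.label <- unname(relabel[tr$tip.label])
  m2 <- clusterCounts(tab); colnames(m2) <- unname(relabel[colnames(m2)])
  sc2 <- sort(unname(clusterCost(wagnerParsimony(ClusterTable(counts = m2),
                                                 tr2))))
  expect_equal(sc1, sc2)
})

test_that("multi-strain species collapse by maximum count", {
  tr <- validateTimeTree(ape::read.tree(text = "((AB:1,C:1):1,D:1);"))
  part <- CladePartition(c(A1 = "X", A2 = "X", C = "X", D = "OUTGROUP"),
                         species = c(A1 = "AB", A2 = "AB", C = "C",
                                     D = "D"))
  m <- rbind(K = c(A1 = 2, A2 = 5, C = 1, D = 0))
  gl <- wagnerParsimony(ClusterTable(counts = m), tr, mode = "count",
                        partition = part)
  expect_equal(unname(nodeStates(gl)["AB", "K"]), 5L)
})
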