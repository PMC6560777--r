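mkTable <- function(m) ClusterTable(counts = m)

test_that("core requires presence in every ingroup species, strains ORed", {
  m <- rbind(C1 = c(A1 = 1, A2 = 0, B = 2, C = 1),
             C2 = c(A1 = 0, A2 = 0, B = 1, C = 1),
             C3 = c(A1 = 1, A2 = 1, B = 1, C = 1))
  tab <- mkTable(m)
  part <- CladePartition(c(A1 = "X", A2 = "X", B = "X", C = "Y"),
                         species = c(A1 = "A", A2 = "A", B = "B", C = "C"))
  expect_setequal(coreClusters(tab, part), c("C1", "C3"))  # C1: strain OR
  expect_setequal(coreClusters(tab, c("B", "C")), c("C1", "C2", "C3"))
  expect_error(coreClusters(tab, character(0)), "empty")
  expect_error(coreClusters(tab, c("B", "ZZ")), "ZZ")
})

test_that("single-copy filter matches a brute-force row scan", {
  expect_setequal(
    singleCopyOrthologs(mkTable(rbind(S1 = c(A = 1, B = 1, C = 1))),
                        c("A", "B", "C")), "S1")
  expect_length(
    singleCopyOrthologs(mkTable(rbind(S1 = c(A = 2, B = 1, C = 1))),
                        c("A", "B", "C")), 0L)
  set.seed(17)
  taxa <- LETTERS[1:6]
  for (rep in 1:50) {
    tab <- randomPresenceTable(10, taxa, pPresent = 0.7, maxCount = 3L)
    got <- singleCopyOrthologs(tab, taxa, allowMissing = 1L)
    cts <- clusterCounts(tab)
    want <- rownames(cts)[apply(cts, 1, function(r)
      all(r <= 1) && sum(r == 1) >= length(taxa) - 1)]
    expect_setequal(got, want)
  }
})

test_that("subset specificity follows the all-but-one rule", {
  m <- rbind(C1 = c(A = 1, B = 1, C = 1, D = 0, E = 0),
             C2 = c(A = 1, B = 1, C = 1, D = 1, E = 0),
             C3 = c(A = 1, B = 1, C = 1, D = 0, E = 1),
             C4 = c(A = 0, B = 0, C = 1, D = 0, E = 0))
  tab <- mkTable(m)
  got <- subsetSpecific(tab, c("A", "B", "C", "D"))
  expect_setequal(got, c("C1", "C2"))       # C3 leaks outside, C4 too few
  expect_error(subsetSpecific(tab, LETTERS[1:5]), "no outside")
  expect_error(subsetSpecific(tab, character(0)), "empty")
})

test_that("clade classification matches a brute-force recomputation", {
  set.seed(29)
  taxa <- c("a1", "a2", "b1", "b2", "c1", "c2", "o1")
  part <- CladePartition(c(a1 = "P", a2 = "P", b1 = "Q", b2 = "Q",
                           c1 = "R", c2 = "R", o1 = "OUTGROUP"))
  for (rep in 1:60) {
    tab <- randomPresenceTable(12, taxa, pPresent = 0.45)
    res <- classifyByClade(tab, part)
    cts <- clusterCounts(tab)
    ing <- c("a1", "a2", "b1", "b2", "c1", "c2")
    cl <- c(a1 = "P", a2 = "P", b1 = "Q", b2 = "Q", c1 = "R", c2 = "R")
    for (k in rownames(cts)) {
      sp <- ing[cts[k, ing] >= 1]
      want <- if (length(sp) == 0) "outgroup_shared"
        else if (length(sp) == length(ing)) "genus_wide"
        else if (length(unique(cl[sp])) >= 2) "multi_clade"
        else if (length(sp) >= 2) "clade_only"
        else "species_only"
      expect_identical(
        res$categories$category[res$categories$cluster_id == k], want)
    }
    # categories partition the clusters
    expect_equal(sum(table(res$categories$category)), nrow(cts))
    # per-species summary columns against direct counting
    for (s in ing) {
      has <- cts[, s] >= 1
      row <- res$summary[res$summary$species == s, ]
      expect_equal(row$present_in, sum(has))
      twoEach <- apply(cts[, ing, drop = FALSE] >= 1, 1, function(p)
        all(vapply(unique(cl), function(g)
          sum(p[cl == g]) >= 2, TRUE)))
      expect_equal(row$two_per_clade, sum(has & twoEach))
      anyIng <- rowSums(cts[, ing, drop = FALSE] >= 1) >= 1
      expect_equal(row$absent_from, sum(anyIng & !has))
      expect_equal(row$total_genes, sum(cts[, s]))
    }
  }
})

test_that("clade classification is invariant under column permutation", {
  set.seed(31)
  taxa <- c("a1", "a2", "b1", "b2", "o1")
  part <- CladePartition(c(a1 = "P", a2 = "P", b1 = "Q", b2 = "Q",
                           o1 = "OUTGROUP"))
  tab <- randomPresenceTable(15, taxa, pPresent = 0.5)
  perm <- mkTable(clusterCounts(tab)[, sample(taxa)])
  r1 <- classifyByClade(tab, part)$categories
  r2 <- classifyByClade(perm, part)$categories
  expect_identical(r1[order(r1$cluster_id), ], r2[order(r2$cluster_id), ])
})

test_that("intersection counts reconcile with brute-force enumeration", {
  set.seed(37)
  taxa <- LETTERS[1:6]
  groups <- list(G1 = c("A", "B"), G2 = c("C", "D"), G3 = c("E", "F", "A"))
  for (rep in 1:40) {
    tab <- randomPresenceTable(20, taxa, pPresent = 0.4)
    res <- intersectionCounts(tab, groups)
    pres <- clusterCounts(tab) >= 1
    inG <- sapply(groups, function(tx) rowSums(pres[, tx, drop = FALSE]) > 0)
    for (i in seq_len(nrow(res))) {
      incl <- strsplit(res$combination[i], "&", fixed = TRUE)[[1]]
      excl <- setdiff(names(groups), incl)
      want <- sum(apply(inG, 1, function(r)
        all(r[incl]) && !any(r[excl])))
      expect_equal(res$count[i], want)
    }
    expect_equal(sum(res$count), sum(rowSums(inG) > 0))
  }
  expect_error(intersectionCounts(tab, rep(list("A"), 13)), "12")
})

test_that("strain differences count private and shared genes", {
  m <- rbind(C1 = c(A = 3, B = 2), C2 = c(A = 2, B = 0),
             C3 = c(A = 0, B = 4))
  tab <- mkTable(m)
  d <- strainDifference(tab, "A", "B")
  expect_equal(d$n_a_only, 2); expect_equal(d$n_b_only, 4)
  expect_equal(d$n_shared_a, 3); expect_equal(d$n_shared_b, 2)
  ident <- strainDifference(tab, "A", "A")
  expect_equal(ident$n_a_only, 0)
  expect_error(strainDifference(tab, "A", "Z"), "Z")
})

test_that("abundance screen computes shares and classes", {
  rec <- data.frame(species = c("s1", "s2", "s3"), n = c(900, 60, 40))
  out <- screenSpeciesAbundance(rec)
  expect_equal(out$share_pct[out$species == "s1"], 90)
  expect_identical(out$class, c("common", "intermediate", "rare"))
  one <- screenSpeciesAbundance(data.frame(species = "only", n = 5))
  expect_equal(one$share_pct, 100)
  expect_error(screenSpeciesAbundance(data.frame(species = "x", n = 0)),
               "zero")
})
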