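test_that("p-distance removes gap/X sites and counts mismatches", {
  expect_equal(pDistance(strrep("A", 100), strrep("A", 100))$p, 0)
  a <- paste0(strrep("A", 90), strrep("W", 10))
  b <- strrep("A", 100)
  expect_equal(pDistance(a, b)$p, 0.10)
  # brute-force site loop on random gapped pairs
  set.seed(67)
  alpha <- c("A", "R", "N", "D", "-", "X")
  for (rep in 1:30) {
    x <- sample(alpha, 80, TRUE); y <- sample(alpha, 80, TRUE)
    keep <- !(x %in% c("-", "X") | y %in% c("-", "X"))
    if (!any(keep)) next
    want <- sum(x[keep] != y[keep]) / sum(keep)
    got <- pDistance(paste(x, collapse = ""), paste(y, collapse = ""))
    expect_equal(got$p, want)
    expect_equal(got$n_sites, sum(keep))
  }
  expect_error(pDistance("A", "AB"), "length")
  expect_error(pDistance("-X", "AA"), "sites")
})

test_that("corrected distances obey ordering, limits and zero identity", {
  expect_equal(poissonDistance(0), 0)
  expect_equal(gammaDistance(0), 0)
  grid <- seq(0.01, 0.7, by = 0.01)
  dp <- poissonDistance(grid)
  dg <- gammaDistance(grid, alpha = 4)
  expect_true(all(dg >= dp & dp >= grid))
  expect_true(all(diff(dp) > 0) && all(diff(dg) > 0))
  # alpha -> Inf limit approaches the Poisson correction
  expect_lt(abs(gammaDistance(0.3, alpha = 1e6) - poissonDistance(0.3)),
            1e-4)
  # decreasing in alpha for fixed p
  alphas <- c(0.5, 1, 2, 4, 16, 64)
  expect_true(all(diff(vapply(alphas, function(a)
    gammaDistance(0.3, a), 0)) < 0))
  expect_error(poissonDistance(1), "\\[0, 1\\)")
  expect_error(gammaDistance(1.2), "\\[0, 1\\)")
})

test_that("mean ortholog identity is 100 for identical proteomes and
           decreases with divergence", {
  pp <- smallProteomePair()
  members <- list(C1 = data.frame(taxon = c("A", "B"),
                                  protein = c("p1", "q1")),
                  C2 = data.frame(taxon = c("A", "B"),
                                  protein = c("p2", "q2")))
  tab <- ClusterTable(members = members)
  M <- meanOrthologSimilarity(list(A = pp$a, B = pp$b), tab)
  expect_equal(M["A", "B"], 100)
  expect_equal(diag(M), c(A = 100, B = 100))

  tr <- ape::read.tree(text = "(A:50,B:50);")
  sims <- vapply(c(2e-4, 1e-3, 3e-3), function(dv) {
    st <- simulateStudy(simConfig(tree = tr, partition = NULL,
                                  gainRate = 0, lossRate = 0,
                                  nRootFamilies = 8,
                                  nPlanted = c(core = 0),
                                  divergenceScale = dv, seed = 71),
                        plantSscp = FALSE, makeGeneMap = FALSE)
    meanOrthologSimilarity(st$proteomes, st$table)["A", "B"]
  }, 0)
  expect_true(all(diff(sims) < 0))
})

test_that("NG86 base cases: identity, forced synonymous, symmetry", {
  r <- ng86dNdS(strrep("ATG", 20), strrep("ATG", 20))
  expect_equal(r$dN, 0); expect_equal(r$dS, 0)
  expect_true(is.na(r$omega))
  r2 <- ng86dNdS("TTTGCT", "TTCGCT", jc = FALSE)
  expect_equal(r2$Sd, 1); expect_equal(r2$Nd, 0)
  set.seed(73)
  for (rep in 1:10) {
    a <- randomCodingSeq(25); b <- randomCodingSeq(25)
    ra <- ng86dNdS(a, b, jc = FALSE); rb <- ng86dNdS(b, a, jc = FALSE)
    expect_equal(ra$Sd, rb$Sd); expect_equal(ra$Nd, rb$Nd)
    expect_equal(ra$S, rb$S)
  }
  expect_error(ng86dNdS("TAAGCT", "TTTGCT"), "stop")
})

test_that("NG86 agrees with naive pathway enumeration to 1e-9", {
  set.seed(79)
  for (rep in 1:25) {
    # mildly diverged pairs keep proportions inside the correctable range
    cp <- simulateCodonPair(stats::runif(1, 0.2, 2), t = 0.5,
                            nCodons = 30, seed = 1000 + rep)
    got <- ng86dNdS(cp)
    want <- naiveNG86(cp$a, cp$b)
    expect_equal(got$N, want$N, tolerance = 1e-9)
    expect_equal(got$S, want$S, tolerance = 1e-9)
    expect_equal(got$Nd, want$Nd, tolerance = 1e-9)
    expect_equal(got$Sd, want$Sd, tolerance = 1e-9)
    expect_equal(got$dN, want$dN, tolerance = 1e-9)
    expect_equal(got$dS, want$dS, tolerance = 1e-9)
  }
})

test_that("selection regimes classify omega with a neutral band", {
  expect_identical(selectionClass(0.2), "purifying")
  expect_identical(selectionClass(1.0), "neutral")
  expect_identical(selectionClass(c(0.95, 1.4, NA)),
                   c("neutral", "diversifying", "undefined"))
  expect_identical(selectionClass(0.85, tau = 0.2), "neutral")
})

test_that("simulated selection regimes are recovered from sequence pairs", {
  set.seed(83)
  oms <- vapply(1:8, function(i)
    ng86dNdS(simulateCodonPair(1, t = 0.4, nCodons = 3000,
                               seed = 300 + i))$omega, 0)
  expect_true(mean(oms) > 0.9 && mean(oms) < 1.1)
  omsP <- vapply(1:8, function(i)
    ng86dNdS(simulateCodonPair(0.1, t = 0.4, nCodons = 3000,
                               seed = 400 + i))$omega, 0)
  expect_true(all(selectionClass(omsP) == "purifying"))
})
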