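# Independent oracles used to freeze expected values. These deliberately
# re-derive results by brute force / naive enumeration, sharing no code with
# the package implementations they check.

# ---- exhaustive minimal-change cost on a rooted tree (binary states) -------
# tree: ape phylo; pattern: named 0/1 vector by tip label.
bruteForceWagnerCost <- function(tree, patterns) {
  ntip <- length(tree$tip.label)
  nint <- tree$Nnode
  E <- tree$edge
  if (is.matrix(patterns)) P <- patterns else P <- matrix(patterns, ncol = 1)
  # P: ntip x K in tree tip order
  best <- rep(Inf, ncol(P))
  for (mask in 0:(2^nint - 1)) {
    internal <- as.integer(intToBits(mask))[seq_len(nint)]
    states <- rbind(P, matrix(rep(internal, ncol(P)), nrow = nint))
    cost <- colSums(abs(states[E[, 1], , drop = FALSE] -
                          states[E[, 2], , drop = FALSE]))
    best <- pmin(best, cost)
  }
  best
}

# ---- union-find connected components ---------------------------------------
unionFindComponents <- function(nVertices, edges) {
  parent <- seq_len(nVertices)
  root <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  if (nrow(edges)) for (k in seq_len(nrow(edges))) {
    a <- root(edges[k, 1]); b <- root(edges[k, 2])
    if (a != b) parent[a] <- b
  }
  length(unique(vapply(seq_len(nVertices), root, 0L)))
}

# ---- naive NG86 (recursive pathway enumeration) ----------------------------
.gcode <- Biostrings::GENETIC_CODE
.stops <- names(.gcode)[.gcode == "*"]

naiveSynSites <- function(codon) {
  ch <- strsplit(codon, "")[[1]]
  total <- 0
  for (pos in 1:3) {
    syn <- 0; nonstop <- 0
    for (n in c("T", "C", "A", "G")) {
      if (n == ch[pos]) next
      alt <- ch; alt[pos] <- n
      alt <- paste(alt, collapse = "")
      if (alt %in% .stops) next
      nonstop <- nonstop + 1
      if (.gcode[[alt]] == .gcode[[codon]]) syn <- syn + 1
    }
    if (nonstop > 0) total <- total + syn / nonstop
  }
  total
}

# all stop-free substitution pathways between two codons, recursively
naivePathCounts <- function(c1, c2) {
  diffs <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  if (!length(diffs)) return(c(0, 0))
  recurse <- function(cur, remaining) {
    if (!length(remaining)) return(list(c(0, 0)))
    out <- list()
    for (p in remaining) {
      ch <- strsplit(cur, "")[[1]]
      ch[p] <- strsplit(c2, "")[[1]][p]
      nxt <- paste(ch, collapse = "")
      if (nxt %in% .stops) next
      step <- if (.gcode[[cur]] == .gcode[[nxt]]) c(1, 0) else c(0, 1)
      for (tail in recurse(nxt, setdiff(remaining, p)))
        out[[length(out) + 1]] <- step + tail
    }
    out
  }
  paths <- recurse(c1, diffs)
  if (!length(paths)) {          # all pathways blocked by stops
    recurse2 <- function(cur, remaining) {
      if (!length(remaining)) return(list(c(0, 0)))
      out <- list()
      for (p in remaining) {
        ch <- strsplit(cur, "")[[1]]
        ch[p] <- strsplit(c2, "")[[1]][p]
        nxt <- paste(ch, collapse = "")
        a1 <- if (cur %in% .stops) "*" else .gcode[[cur]]
        a2 <- if (nxt %in% .stops) "*" else .gcode[[nxt]]
        step <- if (identical(a1, a2)) c(1, 0) else c(0, 1)
        for (tail in recurse2(nxt, setdiff(remaining, p)))
          out[[length(out) + 1]] <- step + tail
      }
      out
    }
    paths <- recurse2(c1, diffs)
  }
  Reduce(`+`, paths) / length(paths)
}

naiveNG86 <- function(a, b) {
  ca <- substring(a, seq(1, nchar(a), 3), seq(3, nchar(a), 3))
  cb <- substring(b, seq(1, nchar(b), 3), seq(3, nchar(b), 3))
  S <- (sum(vapply(ca, naiveSynSites, 0)) +
          sum(vapply(cb, naiveSynSites, 0))) / 2
  N <- 3 * length(ca) - S
  sd <- 0; nd <- 0
  for (i in seq_along(ca)) {
    d <- naivePathCounts(ca[i], cb[i])
    sd <- sd + d[1]; nd <- nd + d[2]
  }
  pS <- sd / S; pN <- nd / N
  list(N = N, S = S, Sd = sd, Nd = nd, pN = pN, pS = pS,
       dN = -0.75 * log(1 - 4 * pN / 3), dS = -0.75 * log(1 - 4 * pS / 3))
}

# random sense-codon sequence
randomCodingSeq <- function(nCodons) {
  sense <- setdiff(names(.gcode), .stops)
  paste(sample(sense, nCodons, replace = TRUE), collapse = "")
}

# ---- misc fixtures ---------------------------------------------------------
randomPresenceTable <- function(nClusters, taxa, pPresent = 0.5,
                                maxCount = 1L) {
  m <- matrix(
    ifelse(stats::runif(nClusters * length(taxa)) < pPresent,
           sample(seq_len(maxCount), nClusters * length(taxa),
                  replace = TRUE), 0L),
    nrow = nClusters,
    dimnames = list(sprintf("K%03d", seq_len(nClusters)), taxa))
  ClusterTable(counts = m)
}

smallProteomePair <- function() {
  a <- Proteome("A", c(p1 = "MKVLWAALLVTFLAGCQAKVEQAVETEPEPELRQQ",
                       p2 = "MGHHHHHHSSGVDLGTENLYFQSNA"))
  b <- Proteome("B", c(q1 = "MKVLWAALLVTFLAGCQAKVEQAVETEPEPELRQQ",
                       q2 = "MGHHHHHHSSGVDLGTENLYFQSNA"))
  list(a = a, b = b)
}
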