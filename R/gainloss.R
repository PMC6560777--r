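# --- tree helpers -----------------------------------------------------------

# node labels in ape numbering order (tips 1..n, then internal nodes)
allNodeLabels <- function(tree) c(tree$tip.label, tree$node.label)

# collapse strain columns to species by max count (presence collapses by OR,
# which max subsumes); leaves of a dated species tree are species ids
collapseToSpecies <- function(counts, partition) {
  taxa <- colnames(counts)
  sp <- speciesOf(partition, taxa)
  sp[is.na(sp)] <- taxa[is.na(sp)]
  grp <- split(seq_along(taxa), sp)
  out <- vapply(grp, function(i)
    apply(counts[, i, drop = FALSE], 1L, max), numeric(nrow(counts)))
  if (nrow(counts) == 1L)
    out <- matrix(out, nrow = 1L, dimnames = list(rownames(counts),
                                                  names(grp)))
  out
}

leafStateMatrix <- function(table, tree, partition = NULL) {
  cts <- clusterCounts(table)
  # a species-labelled tree gets species-collapsed counts; a strain-labelled
  # tree is used as-is
  if (!is.null(partition) &&
      !setequal(tree$tip.label, colnames(cts))) {
    collapsed <- collapseToSpecies(cts, partition)
    if (setequal(tree$tip.label, colnames(collapsed))) cts <- collapsed
  }
  mismatch <- c(setdiff(tree$tip.label, colnames(cts)),
                setdiff(colnames(cts), tree$tip.label))
  if (length(mismatch))
    stop("tree leaves and table taxa differ: ",
         paste(unique(mismatch), collapse = ", "))
  t(cts[, tree$tip.label, drop = FALSE])   # tips x clusters
}

# --- Wagner (Sankoff) parsimony ---------------------------------------------

#' Wagner parsimony reconstruction of gene-family gains and losses
#'
#' Sankoff dynamic programming on a rooted tree. In `presence` mode,
#' cluster states are 0/1 with unit cost per change; in `count` mode,
#' states are copy numbers 0..max observed with linear cost `|i - j|`
#' (Wagner costs). Ties are broken deterministically by preferring the
#' smaller state, at the root and during top-down state assignment —
#' conservative gain placement. Per-branch gains and losses are parent-to-
#' child state increases/decreases; `gene_gains`/`gene_losses` sum the
#' state differences (in presence mode they equal the cluster counts).
#'
#' @param table a [ClusterTable-class]; its taxa (after optional species
#'   collapse) must equal the tree leaves.
#' @param tree a rooted `phylo`; branch lengths optional here (required by
#'   [branchRates()]).
#' @param mode `"presence"` or `"count"`.
#' @param partition optional [CladePartition-class]; multi-strain species
#'   are collapsed by maximum count before reconstruction and tree leaves
#'   are species.
#' @return a [GainLossMap-class].
#' @export
wagnerParsimony <- function(table, tree, mode = c("presence", "count"),
                            partition = NULL) {
  mode <- match.arg(mode)
  tree <- validateTimeTree(tree, requireLengths = FALSE)
  X <- leafStateMatrix(table, tree, partition)
  if (mode == "presence") X <- (X >= 1L) * 1L
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  po <- ape::reorder.phylo(tree, "postorder")
  E <- po$edge
  K <- ncol(X)
  labels <- allNodeLabels(tree)
  if (mode == "presence") {
    C0 <- matrix(0, nnode, K); C1 <- matrix(0, nnode, K)
    C0[seq_len(ntip), ] <- ifelse(X == 0L, 0, Inf)
    C1[seq_len(ntip), ] <- ifelse(X == 1L, 0, Inf)
    for (e in seq_len(nrow(E))) {
      p <- E[e, 1L]; ch <- E[e, 2L]
      C0[p, ] <- C0[p, ] + pmin(C0[ch, ], C1[ch, ] + 1)
      C1[p, ] <- C1[p, ] + pmin(C1[ch, ], C0[ch, ] + 1)
    }
    root <- E[nrow(E), 1L]
    states <- matrix(0L, nnode, K)
    states[seq_len(ntip), ] <- X
    states[root, ] <- ifelse(C0[root, ] <= C1[root, ], 0L, 1L)
    for (e in rev(seq_len(nrow(E)))) {     # preorder
      p <- E[e, 1L]; ch <- E[e, 2L]
      if (ch <= ntip) next
      ps <- states[p, ]
      c0 <- C0[ch, ] + (ps == 1L)
      c1 <- C1[ch, ] + (ps == 0L)
      states[ch, ] <- ifelse(c0 <= c1, 0L, 1L)
    }
    cost <- pmin(C0[root, ], C1[root, ])
  } else {
    maxS <- apply(X, 2L, max)
    states <- matrix(0L, nnode, K)
    cost <- numeric(K)
    for (k in seq_len(K)) {
      M <- maxS[k]
      S <- M + 1L
      C <- matrix(0, nnode, S)
      for (tip in seq_len(ntip))
        C[tip, ] <- ifelse(seq_len(S) - 1L == X[tip, k], 0, Inf)
      for (e in seq_len(nrow(E))) {
        p <- E[e, 1L]; ch <- E[e, 2L]
        inc <- vapply(seq_len(S) - 1L, function(s)
          min(C[ch, ] + abs(s - (seq_len(S) - 1L))), 0)
        C[p, ] <- C[p, ] + inc
      }
      root <- E[nrow(E), 1L]
      states[root, k] <- which.min(C[root, ]) - 1L   # which.min: first = smallest
      for (e in rev(seq_len(nrow(E)))) {
        p <- E[e, 1L]; ch <- E[e, 2L]
        if (ch <= ntip) { states[ch, k] <- X[ch, k]; next }
        tot <- C[ch, ] + abs((seq_len(S) - 1L) - states[p, k])
        states[ch, k] <- which.min(tot) - 1L
      }
      cost[k] <- min(C[root, ])
    }
  }
  rownames(states) <- labels
  colnames(states) <- colnames(X)
  names(cost) <- colnames(X)
  branches <- branchTable(tree, states)
  new("GainLossMap", mode = mode, states = states, branches = branches,
      clusterCost = cost)
}

branchTable <- function(tree, states) {
  labels <- allNodeLabels(tree)
  E <- tree$edge
  len <- if (is.null(tree$edge.length)) rep(NA_real_, nrow(E)) else
    tree$edge.length
  diffmat <- states[E[, 2L], , drop = FALSE] - states[E[, 1L], , drop = FALSE]
  data.frame(parent = labels[E[, 1L]], child = labels[E[, 2L]],
             length_mya = len,
             gains = as.integer(rowSums(diffmat > 0L)),
             losses = as.integer(rowSums(diffmat < 0L)),
             gene_gains = as.integer(rowSums(pmax(diffmat, 0L))),
             gene_losses = as.integer(rowSums(pmax(-diffmat, 0L))),
             stringsAsFactors = FALSE)
}

#' Per-branch gene-change rates
#'
#' Adds `rate = (gains + losses) / length_mya` to the branch table of a
#' [GainLossMap-class]. Zero-length or unknown-length branches get `NA`
#' (undefined), never infinity.
#'
#' @param gainloss a [GainLossMap-class].
#' @return the branch data.frame with an extra `rate` column.
#' @export
branchRates <- function(gainloss) {
  br <- branchChanges(gainloss)
  rate <- (br$gains + br$losses) / br$length_mya
  rate[!is.finite(rate)] <- NA_real_
  rate[is.na(br$length_mya) | br$length_mya <= 0] <- NA_real_
  br$rate <- rate
  br
}

# --- Dollo parsimony --------------------------------------------------------

#' Dollo parsimony reconstruction
#'
#' Each cluster is gained exactly once — on the branch leading to the most
#' recent common ancestor of the taxa possessing it — and may subsequently
#' be lost any number of times; losses are placed minimally (one loss per
#' maximal possession-free subtree inside the gain clade).
#'
#' @inheritParams wagnerParsimony
#' @return a [GainLossMap-class] with mode `"dollo"`.
#' @export
dolloParsimony <- function(table, tree, partition = NULL) {
  tree <- validateTimeTree(tree, requireLengths = FALSE)
  X <- (leafStateMatrix(table, tree, partition) >= 1L) * 1L
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  po <- ape::reorder.phylo(tree, "postorder")
  E <- po$edge
  K <- ncol(X)
  # per-node leaf counts of possession, and subtree descendant lists
  children <- split(E[, 2L], E[, 1L])
  desc <- vector("list", nnode)
  nLeavesBelow <- integer(nnode)
  for (v in seq_len(ntip)) { desc[[v]] <- v; nLeavesBelow[v] <- 1L }
  for (e in seq_len(nrow(E))) {
    p <- E[e, 1L]; ch <- E[e, 2L]
    desc[[p]] <- c(desc[[p]], ch, desc[[ch]])
    nLeavesBelow[p] <- nLeavesBelow[p] + nLeavesBelow[ch]
  }
  for (v in (ntip + 1L):nnode) desc[[v]] <- unique(c(v, desc[[v]]))
  nPoss <- matrix(0L, nnode, K)
  nPoss[seq_len(ntip), ] <- X
  for (e in seq_len(nrow(E)))
    nPoss[E[e, 1L], ] <- nPoss[E[e, 1L], ] + nPoss[E[e, 2L], ]
  states <- matrix(0L, nnode, K)
  cost <- numeric(K)
  root <- E[nrow(E), 1L]
  for (k in seq_len(K)) {
    tot <- nPoss[root, k]
    if (tot == 0L) next
    cand <- which(nPoss[, k] == tot)
    m <- cand[which.min(nLeavesBelow[cand])]      # minimal covering clade
    inSub <- desc[[m]]
    present <- inSub[nPoss[inSub, k] >= 1L]
    states[present, k] <- 1L
    # cost: one gain on m's stem (if any) + one loss per present->absent edge
    losses <- sum(states[E[, 1L], k] == 1L & states[E[, 2L], k] == 0L &
                    E[, 1L] %in% inSub)
    cost[k] <- losses + as.integer(m != root)
  }
  labels <- allNodeLabels(tree)
  rownames(states) <- labels
  colnames(states) <- colnames(X)
  names(cost) <- colnames(X)
  new("GainLossMap", mode = "dollo", states = states,
      branches = branchTable(tree, states), clusterCost = cost)
}
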