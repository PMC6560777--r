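# --- default study design ---------------------------------------------------

#' Default dated tree for simulations
#'
#' A 15-leaf ultrametric chronogram (branch lengths in Mya) emulating a
#' genus-scale study design: 13 ingroup strains of 12 species in three
#' clades (SL, HV, ST; the HV clade carries two strains of one species),
#' plus two outgroup taxa. Clade crowns sit at 25-35 Mya, the genus crown
#' at 66 Mya, outgroup splits at 120 and 140 Mya.
#'
#' @return an `ape::phylo` with node labels.
#' @export
defaultTimeTree <- function() {
  nwk <- paste0(
    "(OUT1:140,((((Trees:8,Tpara:8):17,(Tlongi:12,Tcitri:12):13):41,",
    "((((TharzT:5,TharzR:5):15,Tafro:20):10,(Tguiz:15,Tvir:15):15):20,",
    "((Tatro:20,Tgam:20):15,(Tasp:25,Tham:25):10):15):16):54,OUT2:120):20);")
  validateTimeTree(ape::read.tree(text = nwk))
}

#' Default clade partition matching [defaultTimeTree()]
#'
#' @return a [CladePartition-class] with clades SL, HV, ST and two
#'   outgroups; the two `Tharz*` strains map to one species.
#' @export
defaultCladePartition <- function() {
  clades <- c(Trees = "SL", Tpara = "SL", Tlongi = "SL", Tcitri = "SL",
              TharzT = "HV", TharzR = "HV", Tafro = "HV", Tguiz = "HV",
              Tvir = "HV",
              Tatro = "ST", Tgam = "ST", Tasp = "ST", Tham = "ST",
              OUT1 = "OUTGROUP", OUT2 = "OUTGROUP")
  species <- stats::setNames(names(clades), names(clades))
  species[c("TharzT", "TharzR")] <- "Tharz"
  CladePartition(clades, species = species)
}

#' Simulation configuration
#'
#' Bundles every knob of the synthetic-data generator. A fixed seed makes
#' all downstream outputs byte-identical; sub-generators draw from
#' deterministic offsets of the one seed.
#'
#' @param tree dated tree (default [defaultTimeTree()]).
#' @param partition clade partition (default [defaultCladePartition()];
#'   NULL disables clade/genus plantings).
#' @param gainRate new-family arrivals per Mya per branch.
#' @param lossRate loss events per family per Mya.
#' @param nRootFamilies families present at the root.
#' @param nPlanted named counts of planted categories: `core`, `clade`
#'   (per clade), `genus_orphan`, `species_orphan`, `sscp`, `hydrophobin`,
#'   `ceratoplatanin`, `decoy`.
#' @param meanProteinLen mean emitted protein length (residues).
#' @param divergenceScale per-site substitution probability per Mya of
#'   ancestor-to-leaf path.
#' @param seed integer master seed.
#' @return a list of class `SimConfig`.
#' @export
simConfig <- function(tree = defaultTimeTree(),
                      partition = defaultCladePartition(),
                      gainRate = 0.05, lossRate = 0.002,
                      nRootFamilies = 60,
                      nPlanted = c(core = 15, clade = 4, genus_orphan = 6,
                                   species_orphan = 6, sscp = 5,
                                   hydrophobin = 4, ceratoplatanin = 3,
                                   decoy = 6),
                      meanProteinLen = 120, divergenceScale = 5e-4,
                      seed = 1L) {
  stopifnot(gainRate >= 0, lossRate >= 0, nRootFamilies >= 0,
            all(nPlanted >= 0), meanProteinLen >= 60, divergenceScale >= 0)
  tree <- validateTimeTree(tree)
  structure(list(tree = tree, partition = partition, gainRate = gainRate,
                 lossRate = lossRate, nRootFamilies = nRootFamilies,
                 nPlanted = nPlanted, meanProteinLen = meanProteinLen,
                 divergenceScale = divergenceScale,
                 seed = as.integer(seed)),
            class = "SimConfig")
}

plantedCount <- function(config, what) {
  n <- config$nPlanted
  if (what %in% names(n)) as.integer(n[[what]]) else 0L
}

# --- gene-family gain/loss simulation ---------------------------------------

#' Simulate gene-family evolution on a dated tree
#'
#' Forward simulation of family presence/absence: every root family
#' descends along each branch and is lost with probability
#' `1 - exp(-lossRate * b)` on a branch of length `b` (at most one loss per
#' branch per family); new families arise on each branch as a Poisson draw
#' with mean `gainRate * b` and are inherited by all descendants absent
#' later loss. Planted categories are forced: `core` families are present
#' in every leaf and never lost; `clade` families exactly in one clade's
#' taxa; `genus_orphan` families in all ingroup taxa and no outgroup;
#' `species_orphan` families in a single taxon (assigned round-robin over
#' the ingroup).
#'
#' @param config a [simConfig()].
#' @return list with `table` (presence/absence [ClusterTable-class],
#'   counts-only) and `truth` (list: `category`, `originNode` — child node
#'   of the branch each family arose on, `NA` for root/planted-core —,
#'   `branchGains`, `branchLosses` named by child node, and the `presence`
#'   matrix).
#' @export
simulateFamilyEvolution <- function(config) {
  tree <- config$tree
  if (is.null(tree$edge.length)) stop("tree without branch lengths")
  set.seed(config$seed + 1L)
  labels <- allNodeLabels(tree)
  ntip <- length(tree$tip.label)
  po <- ape::reorder.phylo(tree, "postorder")
  E <- po$edge[rev(seq_len(nrow(po$edge))), , drop = FALSE]   # preorder
  lenE <- po$edge.length[rev(seq_len(nrow(po$edge)))]
  root <- E[1L, 1L]
  childLab <- labels[E[, 2L]]
  branchGains <- stats::setNames(integer(nrow(E)), childLab)
  branchLosses <- stats::setNames(integer(nrow(E)), childLab)

  fams <- list()   # per family: origin node index, origin child-label or NA
  presentAt <- list()  # node index -> character vector of family ids
  nb <- 0L
  newFam <- function() { nb <<- nb + 1L; sprintf("F%04d", nb) }
  rootFams <- vapply(seq_len(max(config$nRootFamilies, 0L)),
                     function(i) newFam(), "")
  presentAt[[root]] <- rootFams
  origin <- stats::setNames(rep(NA_character_, length(rootFams)), rootFams)
  for (e in seq_len(nrow(E))) {
    p <- E[e, 1L]; ch <- E[e, 2L]; b <- lenE[e]
    inherited <- presentAt[[p]]
    if (is.null(inherited)) inherited <- character()
    if (length(inherited) && config$lossRate > 0) {
      keep <- stats::runif(length(inherited)) <
        exp(-config$lossRate * b)
      branchLosses[childLab[e]] <- sum(!keep)
      inherited <- inherited[keep]
    }
    nNew <- stats::rpois(1L, config$gainRate * b)
    gained <- character()
    if (nNew > 0L) {
      gained <- vapply(seq_len(nNew), function(i) newFam(), "")
      origin[gained] <- childLab[e]
      branchGains[childLab[e]] <- branchGains[childLab[e]] + nNew
    }
    presentAt[[ch]] <- c(inherited, gained)
  }
  famIds <- sprintf("F%04d", seq_len(nb))
  presence <- matrix(0L, length(famIds), ntip,
                     dimnames = list(famIds, tree$tip.label))
  for (tip in seq_len(ntip)) {
    f <- presentAt[[tip]]
    if (length(f)) presence[f, tip] <- 1L
  }
  category <- stats::setNames(rep("background", length(famIds)), famIds)

  part <- config$partition
  addPlanted <- function(presence, category, origin, ids, pattern, cat,
                         orig) {
    add <- matrix(0L, length(ids), ntip,
                  dimnames = list(ids, tree$tip.label))
    add[, pattern] <- 1L
    category[ids] <- cat
    origin[ids] <- orig
    list(presence = rbind(presence, add), category = category,
         origin = origin)
  }
  mkIds <- function(prefix, n) if (n > 0) sprintf("%s%03d", prefix,
                                                  seq_len(n)) else character()
  stemChild <- function(taxa) {
    # child-node label of the branch subtending the MRCA of `taxa`
    if (length(taxa) == 1L) return(taxa)
    m <- ape::getMRCA(tree, taxa)
    if (m == root) return(NA_character_)
    labels[m]
  }
  nCore <- plantedCount(config, "core")
  if (nCore > 0L) {
    ids <- mkIds("CORE", nCore)
    r <- addPlanted(presence, category, origin, ids, tree$tip.label,
                    "core", NA_character_)
    presence <- r$presence; category <- r$category; origin <- r$origin
  }
  if (!is.null(part)) {
    ing <- intersect(ingroupTaxa(part), tree$tip.label)
    nClade <- plantedCount(config, "clade")
    if (nClade > 0L) {
      for (cl in cladeLabels(part)) {
        tx <- intersect(cladeTaxa(part, cl), tree$tip.label)
        if (!length(tx)) next
        ids <- mkIds(paste0("CL", cl, "_"), nClade)
        orig <- stemChild(tx)
        r <- addPlanted(presence, category, origin, ids, tx,
                        paste0("clade_", cl), orig)
        presence <- r$presence; category <- r$category; origin <- r$origin
        if (!is.na(orig) && orig %in% names(branchGains))
          branchGains[orig] <- branchGains[orig] + length(ids)
      }
    }
    nGen <- plantedCount(config, "genus_orphan")
    if (nGen > 0L && length(ing)) {
      ids <- mkIds("GORPH", nGen)
      orig <- stemChild(ing)
      r <- addPlanted(presence, category, origin, ids, ing,
                      "genus_orphan", orig)
      presence <- r$presence; category <- r$category; origin <- r$origin
      if (!is.na(orig) && orig %in% names(branchGains))
        branchGains[orig] <- branchGains[orig] + length(ids)
    }
    nSp <- plantedCount(config, "species_orphan")
    if (nSp > 0L && length(ing)) {
      hosts <- rep(ing, length.out = nSp)
      ids <- mkIds("SORPH", nSp)
      for (i in seq_len(nSp)) {
        r <- addPlanted(presence, category, origin, ids[i], hosts[i],
                        paste0("species_orphan_", hosts[i]), hosts[i])
        presence <- r$presence; category <- r$category; origin <- r$origin
        branchGains[hosts[i]] <- branchGains[hosts[i]] + 1L
      }
    }
  }
  table <- ClusterTable(counts = presence)
  truth <- list(category = category, originNode = origin,
                branchGains = branchGains, branchLosses = branchLosses,
                presence = presence, tree = tree, partition = part)
  list(table = table, truth = truth)
}

# --- sequence emission ------------------------------------------------------

randomAA <- function(n, alphabet = AA_ALPHABET20) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

mutateAA <- function(seq, p, alphabet = AA_ALPHABET20) {
  if (p <= 0) return(seq)
  ch <- strsplit(seq, "", fixed = TRUE)[[1L]]
  hit <- which(stats::runif(length(ch)) < p)
  for (i in hit) ch[i] <- sample(setdiff(alphabet, ch[i]), 1L)
  paste(ch, collapse = "")
}

#' Emit proteome sequences for a simulated presence table
#'
#' One protein per (taxon, present family). Each family gets an independent
#' random ancestral sequence (i.i.d. residues — unrelated families share no
#' detectable similarity, which is what the orphan definition requires);
#' each leaf copy substitutes sites with probability
#' `divergenceScale x` (Mya path length from the family's origin node to
#' the leaf), capped at 0.9. With `divergenceScale = 0` all members of a
#' family are identical. Protein ids equal the family id within each taxon.
#'
#' @param table presence [ClusterTable-class] from
#'   [simulateFamilyEvolution()].
#' @param truth matching truth list.
#' @param config the [simConfig()].
#' @return named list of [Proteome-class] objects, one per leaf.
#' @export
emitProteomes <- function(table, truth, config) {
  set.seed(config$seed + 2L)
  tree <- config$tree
  labels <- allNodeLabels(tree)
  D <- ape::dist.nodes(tree)
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  pres <- truth$presence
  fams <- rownames(pres)
  lens <- pmax(60L, stats::rpois(length(fams),
                                 max(config$meanProteinLen, 60)))
  anc <- vapply(lens, randomAA, "")
  names(anc) <- fams
  originIdx <- vapply(truth$originNode[fams], function(o)
    if (is.na(o)) root else match(o, labels), 0L)
  out <- list()
  for (tip in seq_len(ntip)) {
    tx <- tree$tip.label[tip]
    have <- fams[pres[, tx] == 1L]
    seqs <- character(length(have))
    names(seqs) <- have
    for (f in have) {
      p <- min(0.9, config$divergenceScale * D[originIdx[[f]], tip])
      seqs[[f]] <- mutateAA(anc[[f]], p)
    }
    out[[tx]] <- Proteome(tx, seqs)
  }
  out
}

# --- SSCP planting ----------------------------------------------------------

AA_NO_C <- setdiff(AA_ALPHABET20, "C")

secretedPrefix <- function() "MKRTQLLLLLLLLATA"          # 16 aa, satisfies i-iii
unsecretedPrefix <- function() "MDEDEDDDDDDDDGTG"        # no K/R in 1-5

# random sequence without cysteines, then C written at `cysAt` (1-based)
seqWithCys <- function(len, cysAt) {
  if (length(cysAt) && (max(cysAt) > len || min(cysAt) < 1L))
    stop("requested cysteine pattern impossible at requested length")
  ch <- sample(AA_NO_C, len, replace = TRUE)
  ch[cysAt] <- "C"
  paste(ch, collapse = "")
}

buildHydrophobin <- function(len, secreted = TRUE) {
  pre <- if (secreted) secretedPrefix() else unsecretedPrefix()
  m <- len - nchar(pre)
  if (m < 40L) stop("requested cysteine pattern impossible at requested length")
  base <- round(seq(4, m - 4, length.out = 8))
  base[3L] <- base[2L] + 1L
  base[7L] <- base[6L] + 1L
  if (any(diff(base) < 1L)) stop("requested cysteine pattern impossible at requested length")
  paste0(pre, seqWithCys(m, base))
}

buildCeratoplatanin <- function(len) {
  pre <- secretedPrefix()
  m <- len - nchar(pre)
  if (m < 16L) stop("requested cysteine pattern impossible at requested length")
  paste0(pre, seqWithCys(m, round(seq(3, m - 3, length.out = 4))))
}

buildGenericSSCP <- function(len) {
  pre <- secretedPrefix()
  m <- len - nchar(pre)
  nc <- max(7L, ceiling(0.055 * len))
  if (nc %in% c(4L, 8L)) nc <- nc + 1L
  if (m < 2L * nc) stop("requested cysteine pattern impossible at requested length")
  paste0(pre, seqWithCys(m, sort(sample(seq_len(m), nc))))
}

#' Plant cysteine-pattern proteins and decoys into a proteome
#'
#' Adds, with truth labels: class-II-type hydrophobins (secreted, < 300 aa,
#' exactly 8 cysteines with the C2/C3 and C6/C7 doublets), cerato-platanins
#' (secreted, exactly 4 cysteines, SSCP-qualifying length), generic SSCPs
#' (secreted, >= 5% cysteine, violating both special patterns) and decoys
#' that each fail exactly one filter leg (too long, cysteine-poor, or
#' unsecreted despite a hydrophobin-like cysteine pattern).
#'
#' @param proteome a [Proteome-class] to augment.
#' @param counts named counts: `hydrophobin`, `ceratoplatanin`, `sscp`,
#'   `decoy`.
#' @param seed integer seed.
#' @return list with `proteome` (augmented) and `truth` (named character:
#'   planted id -> \{hydrophobin, ceratoplatanin, sscp, none\}).
#' @export
plantSSCP <- function(proteome,
                      counts = c(hydrophobin = 4, ceratoplatanin = 3,
                                 sscp = 5, decoy = 6),
                      seed = 1L) {
  set.seed(seed)
  tx <- taxonIds(proteome)
  seqs <- list(); truth <- character()
  getN <- function(w) if (w %in% names(counts)) as.integer(counts[[w]]) else 0L
  for (i in seq_len(getN("hydrophobin"))) {
    id <- sprintf("%s_HFB%02d", tx, i)
    seqs[[id]] <- buildHydrophobin(sample(96:150, 1L))
    truth[[id]] <- "hydrophobin"
  }
  for (i in seq_len(getN("ceratoplatanin"))) {
    id <- sprintf("%s_CP%02d", tx, i)
    seqs[[id]] <- buildCeratoplatanin(sample(60:78, 1L))
    truth[[id]] <- "ceratoplatanin"
  }
  for (i in seq_len(getN("sscp"))) {
    id <- sprintf("%s_SSCP%02d", tx, i)
    seqs[[id]] <- buildGenericSSCP(sample(90:140, 1L))
    truth[[id]] <- "sscp"
  }
  nD <- getN("decoy")
  for (i in seq_len(nD)) {
    id <- sprintf("%s_DEC%02d", tx, i)
    kind <- c("long", "lowcys", "unsecreted")[((i - 1L) %% 3L) + 1L]
    seqs[[id]] <- switch(kind,
      long = paste0(secretedPrefix(),
                    seqWithCys(sample(300:384, 1L),
                               sort(sample(30:280, 20L)))),
      lowcys = paste0(secretedPrefix(),
                      seqWithCys(sample(120:200, 1L), c(10L, 40L))),
      unsecreted = buildHydrophobin(sample(96:150, 1L), secreted = FALSE))
    truth[[id]] <- "none"
  }
  aa <- c(as.character(sequences(proteome)), unlist(seqs))
  list(proteome = Proteome(tx, aa), truth = truth)
}

# --- gene-map layout --------------------------------------------------------

#' Emit a gene map with planted orphan clusters and subtelomeric placements
#'
#' Genes are laid out on fixed slots (`spacing` bp apart, `geneLen` bp
#' long). Orphan genes are planted as maximal runs of the requested sizes —
#' each run separated from other orphans by at least one non-orphan gene —
#' plus singletons; a requested fraction of orphan genes is placed with
#' gene midpoints within `windowBp` of a chromosome end, the rest well
#' inside. All remaining slots are filled with non-orphan genes. The truth
#' records the realized size histogram and subtelomeric count (whole runs
#' are assigned to a zone, so the realized count is the largest achievable
#' not exceeding the request).
#'
#' @param taxon taxon id.
#' @param layout list with `chromLengths` (named), `nSingletons`,
#'   `clusterSizes` (named counts by size, e.g. `c("2" = 6, "8" = 1)`),
#'   `subtelomericFraction`, `windowBp`, `spacing`, `geneLen`.
#' @param orphanIds ids for the orphan genes (default generated); length
#'   must equal the planted total.
#' @param seed integer seed.
#' @return list with `genemap` ([GeneMap-class]) and `truth` (list:
#'   `sizeHistogram`, `nSubtelomeric`, `fraction`, `orphanIds`,
#'   `perGeneSubtelomeric`).
#' @export
emitGeneMap <- function(taxon,
                        layout = list(),
                        orphanIds = NULL, seed = 1L) {
  set.seed(seed)
  def <- list(chromLengths = c(chr1 = 1.6e6, chr2 = 1.4e6, chr3 = 1.2e6),
              nSingletons = 55, clusterSizes = c("2" = 6, "3" = 2, "8" = 1),
              subtelomericFraction = 0.08, windowBp = 1e5,
              spacing = 2000, geneLen = 1000)
  layout <- utils::modifyList(def, layout)
  sizes <- c(rep(1L, layout$nSingletons),
             rep(as.integer(names(layout$clusterSizes)),
                 as.integer(layout$clusterSizes)))
  nOrphans <- sum(sizes)
  if (is.null(orphanIds))
    orphanIds <- sprintf("%s_orph%03d", taxon, seq_len(nOrphans))
  if (length(orphanIds) != nOrphans)
    stop("need ", nOrphans, " orphan ids, got ", length(orphanIds))
  chroms <- names(layout$chromLengths)
  nSlots <- vapply(layout$chromLengths, function(L)
    as.integer((L - layout$geneLen) %/% layout$spacing + 1L), 0L)
  if (sum(nSlots) < 2L * nOrphans + length(sizes))
    stop("layout infeasible: too many genes for the chromosome lengths")
  slotStart <- lapply(chroms, function(ch)
    (seq_len(nSlots[[ch]]) - 1L) * layout$spacing + 1L)
  names(slotStart) <- chroms
  slotMid <- lapply(chroms, function(ch)
    slotStart[[ch]] + (layout$geneLen - 1) / 2)
  names(slotMid) <- chroms
  slotSub <- lapply(chroms, function(ch) {
    L <- layout$chromLengths[[ch]]
    pmin(slotMid[[ch]], L - slotMid[[ch]]) <= layout$windowBp
  })
  names(slotSub) <- chroms
  # assign whole units to the subtelomeric zone until the target is met
  units <- sizes[sample.int(length(sizes))]
  target <- round(layout$subtelomericFraction * nOrphans)
  zone <- character(length(units))
  placedSub <- 0L
  for (i in seq_along(units)) {
    if (placedSub + units[i] <= target) {
      zone[i] <- "sub"; placedSub <- placedSub + units[i]
    } else zone[i] <- "mid"
  }
  occupied <- lapply(chroms, function(ch) rep(FALSE, nSlots[[ch]]))
  names(occupied) <- chroms
  orphanSlot <- list()   # per placement: chrom, slots
  for (i in seq_along(units)) {
    s <- units[i]
    inZone <- zone[i] == "sub"
    cands <- list()
    for (ch in chroms) {
      ok <- slotSub[[ch]] == inZone
      occ <- occupied[[ch]]
      n <- nSlots[[ch]]
      for (st in seq_len(n - s + 1L)) {
        run <- st:(st + s - 1L)
        if (!all(ok[run])) next
        nb <- c(if (st > 1L) st - 1L, if (st + s <= n) st + s)
        if (any(occ[run]) || any(occ[nb])) next
        cands[[length(cands) + 1L]] <- list(ch = ch, run = run)
      }
    }
    if (!length(cands)) stop("layout infeasible: no room for a run of size ",
                             s, " in the ",
                             if (inZone) "subtelomeric" else "middle",
                             " zone")
    pick <- cands[[sample.int(length(cands), 1L)]]
    occupied[[pick$ch]][pick$run] <- TRUE
    orphanSlot[[i]] <- pick
  }
  # lay down all genes
  loci <- list(); usedOrphan <- 0L
  orphanAssigned <- character(0)
  perGeneSub <- logical(0)
  orphanAt <- lapply(chroms, function(ch) rep(NA_character_, nSlots[[ch]]))
  names(orphanAt) <- chroms
  for (i in seq_along(orphanSlot)) {
    p <- orphanSlot[[i]]
    ids <- orphanIds[(usedOrphan + 1L):(usedOrphan + length(p$run))]
    usedOrphan <- usedOrphan + length(p$run)
    orphanAt[[p$ch]][p$run] <- ids
    orphanAssigned <- c(orphanAssigned, ids)
    perGeneSub <- c(perGeneSub, rep(zone[i] == "sub", length(ids)))
  }
  rows <- list()
  for (ch in chroms) {
    ids <- orphanAt[[ch]]
    filler <- is.na(ids)
    ids[filler] <- sprintf("%s_%s_g%04d", taxon, ch, which(filler))
    st <- slotStart[[ch]]
    rows[[ch]] <- data.frame(gene_id = ids, chrom = ch, start = st,
                             end = st + layout$geneLen - 1L,
                             stringsAsFactors = FALSE)
  }
  gm <- GeneMap(taxon, do.call(rbind, rows), layout$chromLengths)
  hist <- table(factor(units, levels = sort(unique(units))))
  truth <- list(
    sizeHistogram = stats::setNames(as.integer(hist), names(hist)),
    nSubtelomeric = placedSub,
    fraction = placedSub / nOrphans,
    orphanIds = orphanAssigned,
    perGeneSubtelomeric = stats::setNames(perGeneSub, orphanAssigned),
    windowBp = layout$windowBp)
  list(genemap = gm, truth = truth)
}

# --- codon-pair simulation --------------------------------------------------

#' Simulate a diverged codon pair under selection
#'
#' Two sequences descend from a random sense-codon ancestor, each evolving
#' for time `t/2`. Nucleotide changes are proposed at rate 1 per site per
#' unit time (transitions weighted `kappa`); a proposal creating a stop
#' codon is rejected, a synonymous proposal is accepted, a nonsynonymous
#' one is accepted with probability `omega`.
#'
#' @param omega relative fixation probability of nonsynonymous changes
#'   (> 0).
#' @param t total divergence time (expected proposals per nucleotide site
#'   along the whole path between the two sequences).
#' @param kappa transition/transversion proposal ratio (default 1).
#' @param nCodons number of codons (sequence length / 3).
#' @param seed integer seed.
#' @return list of class `CodonPair` with elements `a` and `b`.
#' @export
simulateCodonPair <- function(omega, t, kappa = 1, nCodons = 300L,
                              seed = 1L) {
  stopifnot(omega > 0, t > 0, kappa > 0, nCodons >= 1L)
  set.seed(seed)
  tb <- ng86Tables()
  gc <- geneticCode()
  anc <- sample(tb$sense, nCodons, replace = TRUE)
  transitionOf <- c(T = "C", C = "T", A = "G", G = "A")
  evolve <- function(codons, time) {
    nProp <- stats::rpois(1L, 3 * length(codons) * time)
    for (k in seq_len(nProp)) {
      ci <- sample.int(length(codons), 1L)
      pos <- sample.int(3L, 1L)
      cur <- codons[[ci]]
      nuc <- substr(cur, pos, pos)
      alts <- setdiff(NUCS, nuc)
      w <- ifelse(alts == transitionOf[[nuc]], kappa, 1)
      alt <- sample(alts, 1L, prob = w)
      new <- cur
      substr(new, pos, pos) <- alt
      if (new %in% STOP_CODONS) next
      if (gc[[new]] != gc[[cur]] && stats::runif(1L) > omega) next
      codons[[ci]] <- new
    }
    codons
  }
  a <- evolve(anc, t / 2)
  b <- evolve(anc, t / 2)
  structure(list(a = paste(a, collapse = ""), b = paste(b, collapse = "")),
            class = "CodonPair")
}

# --- one-call study simulation ----------------------------------------------

#' Simulate a complete synthetic study
#'
#' Chains [simulateFamilyEvolution()], [emitProteomes()], [plantSSCP()]
#' (into the first ingroup taxon) and [emitGeneMap()] (for the same taxon)
#' into one bundle with full truth labels; the cluster table gains member
#' lists (protein id = family id).
#'
#' @param config a [simConfig()].
#' @param plantSscp plant cysteine-pattern proteins (default TRUE).
#' @param makeGeneMap emit the orphan-layout gene map (default TRUE).
#' @param geneMapLayout layout overrides for [emitGeneMap()].
#' @return list: `config`, `tree`, `partition`, `table` (with members),
#'   `proteomes`, `truth` (family truth plus `$sscp`, `$sscpTaxon`,
#'   `$genemap`), `genemap`.
#' @export
simulateStudy <- function(config = simConfig(), plantSscp = TRUE,
                          makeGeneMap = TRUE, geneMapLayout = list()) {
  fam <- simulateFamilyEvolution(config)
  proteomes <- emitProteomes(fam$table, fam$truth, config)
  truth <- fam$truth
  sscpTaxon <- NULL
  if (plantSscp && !is.null(config$partition)) {
    sscpTaxon <- intersect(ingroupTaxa(config$partition),
                           names(proteomes))[1L]
    pl <- plantSSCP(proteomes[[sscpTaxon]],
                    counts = config$nPlanted[intersect(
                      c("hydrophobin", "ceratoplatanin", "sscp", "decoy"),
                      names(config$nPlanted))],
                    seed = config$seed + 3L)
    proteomes[[sscpTaxon]] <- pl$proteome
    truth$sscp <- pl$truth
    truth$sscpTaxon <- sscpTaxon
  }
  # member lists from presence (protein id = family id)
  pres <- truth$presence
  members <- lapply(rownames(pres), function(f) {
    tx <- colnames(pres)[pres[f, ] == 1L]
    data.frame(taxon = tx, protein = rep(f, length(tx)),
               stringsAsFactors = FALSE)
  })
  names(members) <- rownames(pres)
  table <- ClusterTable(members = members, taxa = colnames(pres))
  genemap <- NULL
  if (makeGeneMap) {
    gmTaxon <- if (!is.null(config$partition))
      intersect(ingroupTaxa(config$partition), colnames(pres))[1L]
      else colnames(pres)[1L]
    gm <- emitGeneMap(gmTaxon, layout = geneMapLayout,
                      seed = config$seed + 4L)
    genemap <- gm$genemap
    truth$genemap <- gm$truth
    truth$genemapTaxon <- gmTaxon
  }
  list(config = config, tree = config$tree, partition = config$partition,
       table = table, proteomes = proteomes, truth = truth,
       genemap = genemap)
}

#' Write a simulated study to a directory
#'
#' Writes `proteomes/<taxon>.faa`, `clusters.groups`, `tree.nwk`,
#' `genemap.tsv`, `clades.tsv` and `truth.json`. Deterministic for a fixed
#' config.
#'
#' @param study result of [simulateStudy()].
#' @param dir output directory (created).
#' @return `dir`, invisibly.
#' @export
writeSimulation <- function(study, dir) {
  dir.create(file.path(dir, "proteomes"), recursive = TRUE,
             showWarnings = FALSE)
  for (p in study$proteomes)
    writeProteome(p, file.path(dir, "proteomes",
                               paste0(taxonIds(p), ".faa")))
  writeGroups(study$table, file.path(dir, "clusters.groups"))
  ape::write.tree(study$tree, file.path(dir, "tree.nwk"))
  if (!is.null(study$genemap))
    writeGeneMap(study$genemap, file.path(dir, "genemap.tsv"))
  if (!is.null(study$partition)) {
    part <- study$partition
    df <- data.frame(taxon = taxonIds(part),
                     clade = unname(cladeOf(part)),
                     species = unname(speciesOf(part)),
                     ingroup = taxonIds(part) %in% ingroupTaxa(part))
    utils::write.table(df, file.path(dir, "clades.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  truth <- study$truth
  truth$tree <- NULL; truth$partition <- NULL
  truth$presence <- NULL
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, null = "null")
  invisible(dir)
}
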