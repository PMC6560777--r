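#' Normalized global similarity of two protein sequences
#'
#' Needleman-Wunsch global alignment with the BLOSUM62 matrix and affine gap
#' penalties, normalized by the self-alignment score of the shorter sequence,
#' clamped into \[0, 1\]. Identical sequences score 1; unrelated sequences
#' score near 0. The scorer is symmetric.
#'
#' @param a,b amino-acid sequence strings (or `AAString`s).
#' @param gapOpening,gapExtension affine gap penalties.
#' @return similarity score in \[0, 1\].
#' @examples
#' pairwiseSimilarity("MKVLW", "MKVLW")
#' @export
pairwiseSimilarity <- function(a, b, gapOpening = 10, gapExtension = 0.5) {
  a <- as.character(a); b <- as.character(b)
  if (!nzchar(a) || !nzchar(b)) stop("empty sequence")
  raw <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b), type = "global",
    substitutionMatrix = "BLOSUM62", gapOpening = gapOpening,
    gapExtension = gapExtension, scoreOnly = TRUE)
  short <- if (nchar(a) <= nchar(b)) a else b
  min(1, max(0, raw / selfScore(short)))
}

# BLOSUM62 self-alignment score (sum of diagonal entries); the normalizer.
selfScore <- function(seq) {
  mat <- getBlosum62()
  ch <- strsplit(seq, "", fixed = TRUE)[[1L]]
  sum(mat[cbind(ch, ch)])
}

.pkgCache <- new.env(parent = emptyenv())

getBlosum62 <- function() {
  if (is.null(.pkgCache$B62)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    .pkgCache$B62 <- e$BLOSUM62
  }
  .pkgCache$B62
}

# unique overlapping k-mers of each sequence
kmerSets <- function(seqs, k = 4L) {
  lapply(seqs, function(s) {
    n <- nchar(s)
    if (n < k) return(character())
    unique(substring(s, 1:(n - k + 1L), k:n))
  })
}

# Sparse cross-proteome similarity: for each query in A, align only against
# subjects in B sharing >= minSharedKmers k-mers (BLAST-like seeding).
# Returns a list of score vectors (named by subject id) per query id.
crossScores <- function(pa, pb, prescreen = TRUE, minSharedKmers = 3L,
                        k = 4L, gapOpening = 10, gapExtension = 0.5) {
  sa <- as.character(sequences(pa)); sb <- as.character(sequences(pb))
  mat <- getBlosum62()
  selfA <- vapply(sa, selfScore, 0)
  selfB <- vapply(sb, selfScore, 0)
  if (prescreen) {
    ka <- kmerSets(sa, k); kb <- kmerSets(sb, k)
    idx <- rep(seq_along(kb), lengths(kb))
    bykmer <- split(idx, unlist(kb))
  }
  out <- vector("list", length(sa))
  names(out) <- names(sa)
  wa <- nchar(sa); wb <- nchar(sb)
  for (i in seq_along(sa)) {
    if (prescreen) {
      hits <- unlist(bykmer[ka[[i]]], use.names = FALSE)
      if (!length(hits)) { out[[i]] <- numeric(); next }
      tab <- tabulate(hits, nbins = length(sb))
      cand <- which(tab >= minSharedKmers)
      if (!length(cand)) { out[[i]] <- numeric(); next }
    } else cand <- seq_along(sb)
    raw <- Biostrings::pairwiseAlignment(
      Biostrings::AAStringSet(sb[cand]), Biostrings::AAString(sa[[i]]),
      type = "global", substitutionMatrix = "BLOSUM62",
      gapOpening = gapOpening, gapExtension = gapExtension, scoreOnly = TRUE)
    norm <- raw / ifelse(wa[i] <= wb[cand], selfA[i], selfB[cand])
    out[[i]] <- stats::setNames(pmin(1, pmax(0, norm)), names(sb)[cand])
  }
  out
}

#' Reciprocal best hits between two proteomes
#'
#' A pair (x, y) is reported iff y is the unique top-scoring hit of x in B,
#' x is the unique top-scoring hit of y in A, and the normalized similarity
#' is at least `minScore`. Ties for the best hit exclude the query. An
#' optional shared-k-mer prescreen (on by default) restricts alignment to
#' plausibly homologous pairs; pairs failing the screen score 0.
#'
#' @param pa,pb two [Proteome-class] objects.
#' @param minScore minimal normalized similarity in (0, 1\] (default 0.5).
#' @param prescreen use the k-mer seeding filter.
#' @param minSharedKmers seeds required to align a pair.
#' @return data.frame with columns `query`, `subject`, `score` (query from
#'   `pa`, subject from `pb`).
#' @export
reciprocalBestHits <- function(pa, pb, minScore = 0.5, prescreen = TRUE,
                               minSharedKmers = 3L) {
  stopifnot(minScore > 0, minScore <= 1)
  sc <- crossScores(pa, pb, prescreen = prescreen,
                    minSharedKmers = minSharedKmers)
  # unique argmax per query; symmetric scorer lets one pass serve both ways
  bestOf <- function(v) {
    if (!length(v)) return(NA_character_)
    m <- max(v)
    top <- names(v)[v == m]
    if (length(top) != 1L) NA_character_ else top
  }
  bestA <- vapply(sc, bestOf, "")          # per query in A: best subject in B
  # invert to per-subject score lists for B's best-in-A
  inv <- list()
  for (q in names(sc)) {
    v <- sc[[q]]
    for (s in names(v)) inv[[s]] <- c(inv[[s]], stats::setNames(v[[s]], q))
  }
  bestB <- vapply(inv, bestOf, "")
  res <- list()
  for (q in names(bestA)) {
    s <- bestA[[q]]
    if (is.na(s)) next
    if (!is.na(bestB[s]) && identical(bestB[[s]], q) &&
        sc[[q]][[s]] >= minScore)
      res[[length(res) + 1L]] <- data.frame(query = q, subject = s,
                                            score = unname(sc[[q]][[s]]),
                                            stringsAsFactors = FALSE)
  }
  if (!length(res))
    return(data.frame(query = character(), subject = character(),
                      score = numeric(), stringsAsFactors = FALSE))
  do.call(rbind, res)
}

#' Build ortholog clusters as connected components of an RBH graph
#'
#' Every protein of every proteome becomes a graph vertex; RBH pairs are
#' edges; clusters are connected components. Proteins without edges become
#' singleton clusters. The cluster id is the lexicographically smallest
#' member (`taxon|protein`), prefixed with `"C_"`.
#'
#' @param hits data.frame with columns `taxon_a`, `protein_a`, `taxon_b`,
#'   `protein_b` (e.g. from [allPairsRBH()]).
#' @param proteomes list of [Proteome-class] objects providing the full
#'   vertex set.
#' @param sep taxon/protein separator used in vertex names.
#' @return a [ClusterTable-class] with member lists.
#' @export
buildClusters <- function(hits, proteomes, sep = "|") {
  verts <- unlist(lapply(proteomes, function(p)
    paste(taxonIds(p), names(sequences(p)), sep = sep)), use.names = FALSE)
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, length(verts), name = verts)
  if (nrow(hits)) {
    ea <- paste(hits$taxon_a, hits$protein_a, sep = sep)
    eb <- paste(hits$taxon_b, hits$protein_b, sep = sep)
    keep <- ea %in% verts & eb %in% verts
    if (any(!keep)) stop("hit references unknown protein: ",
                         paste(unique(c(ea[!keep], eb[!keep]))[1L]))
    g <- igraph::add_edges(g, rbind(match(ea, verts), match(eb, verts)))
  }
  comp <- igraph::components(g)$membership
  byComp <- split(verts, comp)
  ids <- vapply(byComp, function(v) paste0("C_", min(v)), "")
  ord <- order(ids)
  members <- lapply(byComp[ord], function(v) {
    parts <- strsplit(v, sep, fixed = TRUE)
    data.frame(taxon = vapply(parts, `[[`, "", 1L),
               protein = vapply(parts, function(p)
                 paste(p[-1L], collapse = sep), ""),
               stringsAsFactors = FALSE)
  })
  names(members) <- ids[ord]
  ClusterTable(members = members,
               taxa = vapply(proteomes, taxonIds, ""))
}

#' RBH across all proteome pairs
#'
#' Runs [reciprocalBestHits()] for every unordered pair of proteomes and
#' returns the combined edge list.
#'
#' @inheritParams reciprocalBestHits
#' @param proteomes list of [Proteome-class] objects (>= 2).
#' @return data.frame with columns `taxon_a`, `protein_a`, `taxon_b`,
#'   `protein_b`, `score`.
#' @export
allPairsRBH <- function(proteomes, minScore = 0.5, prescreen = TRUE,
                        minSharedKmers = 3L) {
  stopifnot(length(proteomes) >= 2L)
  res <- list()
  for (i in seq_len(length(proteomes) - 1L)) {
    for (j in (i + 1L):length(proteomes)) {
      rb <- reciprocalBestHits(proteomes[[i]], proteomes[[j]],
                               minScore = minScore, prescreen = prescreen,
                               minSharedKmers = minSharedKmers)
      if (nrow(rb))
        res[[length(res) + 1L]] <- data.frame(
          taxon_a = taxonIds(proteomes[[i]]), protein_a = rb$query,
          taxon_b = taxonIds(proteomes[[j]]), protein_b = rb$subject,
          score = rb$score, stringsAsFactors = FALSE)
    }
  }
  if (!length(res))
    return(data.frame(taxon_a = character(), protein_a = character(),
                      taxon_b = character(), protein_b = character(),
                      score = numeric(), stringsAsFactors = FALSE))
  do.call(rbind, res)
}

#' One-step ortholog clustering of a proteome collection
#'
#' Convenience wrapper: all-pairs RBH followed by [buildClusters()].
#'
#' @inheritParams allPairsRBH
#' @return a [ClusterTable-class].
#' @export
clusterProteomes <- function(proteomes, minScore = 0.5, prescreen = TRUE,
                             minSharedKmers = 3L) {
  hits <- allPairsRBH(proteomes, minScore = minScore, prescreen = prescreen,
                      minSharedKmers = minSharedKmers)
  buildClusters(hits, proteomes)
}
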