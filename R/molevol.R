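# --- amino-acid distances ---------------------------------------------------

#' Proportion of differing aligned sites (p-distance)
#'
#' Sites with a gap (`-` or `.`) or an unknown residue (`X`) in either
#' sequence are removed before comparison (pairwise deletion).
#'
#' @param a,b aligned sequences of equal length.
#' @return list with `p` and `n_sites` (sites retained).
#' @export
pDistance <- function(a, b) {
  a <- strsplit(toupper(as.character(a)), "", fixed = TRUE)[[1L]]
  b <- strsplit(toupper(as.character(b)), "", fixed = TRUE)[[1L]]
  if (length(a) != length(b)) stop("aligned sequences differ in length")
  drop <- a %in% c("-", ".", "X") | b %in% c("-", ".", "X")
  a <- a[!drop]; b <- b[!drop]
  if (!length(a)) stop("no aligned sites left after removing gaps/unknowns")
  list(p = mean(a != b), n_sites = length(a))
}

#' Poisson-corrected distance
#'
#' `d = -ln(1 - p)`.
#'
#' @param p proportion of differing sites, in \[0, 1).
#' @return corrected distance.
#' @export
poissonDistance <- function(p) {
  if (any(p < 0 | p >= 1)) stop("p must be in [0, 1)")
  -log(1 - p)
}

#' Gamma-corrected distance
#'
#' `d = alpha * ((1 - p)^(-1/alpha) - 1)`; models among-site rate variation
#' with a gamma distribution of shape `alpha` (default 4). As
#' `alpha -> Inf` this converges to the Poisson correction.
#'
#' @param p proportion of differing sites, in \[0, 1).
#' @param alpha gamma shape parameter (default 4).
#' @return corrected distance.
#' @export
gammaDistance <- function(p, alpha = 4) {
  if (any(p < 0 | p >= 1)) stop("p must be in [0, 1)")
  stopifnot(alpha > 0)
  alpha * ((1 - p)^(-1 / alpha) - 1)
}

#' All three distances for one aligned pair
#'
#' @inheritParams pDistance
#' @param alpha gamma shape parameter.
#' @return one-row data.frame: `p`, `d_poisson`, `d_gamma`, `n_sites`.
#' @export
distanceSummary <- function(a, b, alpha = 4) {
  pd <- pDistance(a, b)
  data.frame(p = pd$p, d_poisson = poissonDistance(pd$p),
             d_gamma = gammaDistance(pd$p, alpha), n_sites = pd$n_sites)
}

#' Mean ortholog percent identity between taxa
#'
#' For each taxon pair, aligns the two members of every spanning
#' single-copy cluster (global alignment) and averages
#' `100 * (1 - p)` over clusters. Diagonal is 100; pairs with no shared
#' cluster are `NA`.
#'
#' @param proteomes named list of [Proteome-class] objects (names = taxa).
#' @param table a [ClusterTable-class] with member lists.
#' @param clusters cluster ids to use (typically from
#'   [singleCopyOrthologs()]); default all single-copy rows.
#' @return symmetric numeric matrix of mean percent identity.
#' @export
meanOrthologSimilarity <- function(proteomes, table, clusters = NULL) {
  if (is.null(names(proteomes)))
    names(proteomes) <- vapply(proteomes, taxonIds, "")
  mem <- clusterMembers(table)
  if (!length(mem)) stop("table has no member lists")
  if (is.null(clusters)) {
    cts <- clusterCounts(table)
    clusters <- rownames(cts)[apply(cts <= 1L, 1L, all)]
  }
  taxa <- names(proteomes)
  M <- matrix(NA_real_, length(taxa), length(taxa),
              dimnames = list(taxa, taxa))
  diag(M) <- 100
  cnt <- matrix(0L, length(taxa), length(taxa),
                dimnames = list(taxa, taxa))
  acc <- matrix(0, length(taxa), length(taxa), dimnames = list(taxa, taxa))
  for (cid in clusters) {
    m <- mem[[cid]]
    m <- m[m$taxon %in% taxa, , drop = FALSE]
    if (nrow(m) < 2L) next
    for (i in seq_len(nrow(m) - 1L)) for (j in (i + 1L):nrow(m)) {
      ti <- m$taxon[i]; tj <- m$taxon[j]
      if (ti == tj) next
      si <- as.character(sequences(proteomes[[ti]])[[m$protein[i]]])
      sj <- as.character(sequences(proteomes[[tj]])[[m$protein[j]]])
      al <- Biostrings::pairwiseAlignment(Biostrings::AAString(si),
                                          Biostrings::AAString(sj),
                                          type = "global",
                                          substitutionMatrix = "BLOSUM62",
                                          gapOpening = 10, gapExtension = 0.5)
      p <- pDistance(as.character(Biostrings::alignedPattern(al)),
                     as.character(Biostrings::alignedSubject(al)))$p
      acc[ti, tj] <- acc[ti, tj] + 100 * (1 - p)
      cnt[ti, tj] <- cnt[ti, tj] + 1L
    }
  }
  for (i in seq_along(taxa)) for (j in seq_along(taxa)) {
    if (i == j) next
    tot <- cnt[i, j] + cnt[j, i]
    if (tot > 0L)
      M[i, j] <- M[j, i] <- (acc[i, j] + acc[j, i]) / tot
  }
  M
}

# --- Nei-Gojobori 1986 dN/dS ------------------------------------------------

NUCS <- c("T", "C", "A", "G")
STOP_CODONS <- c("TAA", "TAG", "TGA")

geneticCode <- function() {
  gc <- Biostrings::GENETIC_CODE
  names(gc) <- names(Biostrings::GENETIC_CODE)
  gc
}

codonAA <- function(codon) unname(geneticCode()[codon])

# fractional synonymous site count of one codon: at each position, the
# fraction of non-stop single-nucleotide changes that are synonymous
codonSynSites <- function(codon) {
  gc <- geneticCode()
  aa <- gc[[codon]]
  ch <- strsplit(codon, "", fixed = TRUE)[[1L]]
  s <- 0
  for (pos in 1:3) {
    alts <- vapply(setdiff(NUCS, ch[pos]), function(n) {
      x <- ch; x[pos] <- n; paste(x, collapse = "")
    }, "")
    alts <- alts[!alts %in% STOP_CODONS]
    if (length(alts))
      s <- s + sum(gc[alts] == aa) / length(alts)
  }
  s
}

# average (Sd, Nd) over all shortest substitution pathways between two
# codons, excluding pathways through stop codons (fall back to all pathways
# if every one is blocked)
codonPairDiff <- function(c1, c2) {
  gc <- geneticCode()
  a <- strsplit(c1, "", fixed = TRUE)[[1L]]
  b <- strsplit(c2, "", fixed = TRUE)[[1L]]
  pos <- which(a != b)
  if (!length(pos)) return(c(Sd = 0, Nd = 0))
  countPath <- function(order) {
    cur <- a; sd <- 0; nd <- 0
    for (p in order) {
      nxt <- cur; nxt[p] <- b[p]
      cod1 <- paste(cur, collapse = ""); cod2 <- paste(nxt, collapse = "")
      if (cod2 %in% STOP_CODONS) return(NULL)   # endpoints are sense codons
      if (gc[[cod1]] == gc[[cod2]]) sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    c(sd, nd)
  }
  orders <- permutationsOf(pos)
  res <- lapply(orders, countPath)
  ok <- !vapply(res, is.null, TRUE)
  if (!any(ok)) {             # every pathway passes a stop; average all
    res <- lapply(orders, function(order) {
      cur <- a; sd <- 0; nd <- 0
      for (p in order) {
        nxt <- cur; nxt[p] <- b[p]
        cod1 <- paste(cur, collapse = ""); cod2 <- paste(nxt, collapse = "")
        aa1 <- if (cod1 %in% STOP_CODONS) "*" else gc[[cod1]]
        aa2 <- if (cod2 %in% STOP_CODONS) "*" else gc[[cod2]]
        if (identical(aa1, aa2)) sd <- sd + 1 else nd <- nd + 1
        cur <- nxt
      }
      c(sd, nd)
    })
    ok <- rep(TRUE, length(res))
  }
  m <- do.call(rbind, res[ok])
  c(Sd = mean(m[, 1L]), Nd = mean(m[, 2L]))
}

permutationsOf <- function(x) {
  if (length(x) == 1L) return(list(x))
  out <- list()
  for (i in seq_along(x))
    for (rest in permutationsOf(x[-i]))
      out[[length(out) + 1L]] <- c(x[i], rest)
  out
}

# cached per-codon site counts and per-codon-pair difference counts
ng86Tables <- function() {
  if (is.null(.pkgCache$ng86)) {
    codons <- as.vector(outer(outer(NUCS, NUCS, paste0), NUCS, paste0))
    sense <- setdiff(codons, STOP_CODONS)
    syn <- vapply(sense, codonSynSites, 0)
    Sd <- matrix(0, length(sense), length(sense),
                 dimnames = list(sense, sense))
    Nd <- Sd
    for (i in seq_along(sense)) for (j in seq_along(sense)) {
      if (i == j) next
      d <- codonPairDiff(sense[i], sense[j])
      Sd[i, j] <- d[["Sd"]]; Nd[i, j] <- d[["Nd"]]
    }
    .pkgCache$ng86 <- list(sense = sense, syn = syn, Sd = Sd, Nd = Nd)
  }
  .pkgCache$ng86
}

splitCodons <- function(seq) {
  seq <- toupper(as.character(seq))
  n <- nchar(seq)
  if (n %% 3 != 0) stop("sequence length not divisible by 3")
  substring(seq, seq(1L, n, 3L), seq(3L, n, 3L))
}

#' Nei-Gojobori (1986) pairwise dN/dS
#'
#' Counts synonymous and nonsynonymous sites per codon by fractional site
#' counting under the standard genetic code (changes to stop codons
#' excluded), averages observed synonymous/nonsynonymous differences over
#' all shortest substitution pathways between differing codons (pathways
#' through stop codons excluded), applies the Jukes-Cantor correction
#' `d = -(3/4) ln(1 - (4/3) p)` to both proportions, and reports
#' `omega = dN / dS` (`NA` when `dS = 0`). Codons containing gaps or
#' ambiguous bases in either sequence are removed pairwise; internal stop
#' codons are an error.
#'
#' @param a,b coding nucleotide sequences, aligned, equal length divisible
#'   by 3. A list with elements `a` and `b` (a codon pair, e.g. from
#'   [simulateCodonPair()]) may be given as the first argument.
#' @param jc apply the Jukes-Cantor correction (default TRUE; proportions
#'   at or beyond 3/4 are then a saturation error). With `jc = FALSE` the
#'   raw site and difference counts are reported and `dN`, `dS`, `omega`
#'   are `NA`.
#' @return one-row data.frame: `N`, `S`, `Nd`, `Sd`, `pN`, `pS`, `dN`,
#'   `dS`, `omega`, `n_codons`.
#' @examples
#' ng86dNdS("TTTGCT", "TTCGCT", jc = FALSE)  # one synonymous difference
#' @export
ng86dNdS <- function(a, b = NULL, jc = TRUE) {
  if (is.list(a) && is.null(b)) { b <- a$b; a <- a$a }
  ca <- splitCodons(a); cb <- splitCodons(b)
  if (length(ca) != length(cb)) stop("sequences differ in codon count")
  keep <- !grepl("[^TCAG]", ca) & !grepl("[^TCAG]", cb)
  ca <- ca[keep]; cb <- cb[keep]
  if (!length(ca)) stop("no comparable codons")
  inStop <- ca %in% STOP_CODONS | cb %in% STOP_CODONS
  if (any(inStop[-length(ca)]) || (length(ca) && inStop[length(ca)] &&
                                   !(ca[length(ca)] == cb[length(ca)])))
    stop("internal stop codon")
  # a shared terminal stop codon is tolerated and dropped
  if (inStop[length(ca)]) { ca <- ca[-length(ca)]; cb <- cb[-length(cb)] }
  tb <- ng86Tables()
  ia <- match(ca, tb$sense); ib <- match(cb, tb$sense)
  if (anyNA(ia) || anyNA(ib)) stop("internal stop codon")
  Sa <- sum(tb$syn[ia]); Sb <- sum(tb$syn[ib])
  S <- (Sa + Sb) / 2
  N <- 3 * length(ca) - S
  Sd <- sum(tb$Sd[cbind(ia, ib)])
  Nd <- sum(tb$Nd[cbind(ia, ib)])
  pS <- if (S > 0) Sd / S else 0
  pN <- if (N > 0) Nd / N else 0
  if (jc) {
    if (pS >= 0.75 || pN >= 0.75)
      stop("substitution saturation: p >= 3/4, ",
           "Jukes-Cantor correction undefined")
    corr <- function(p) -0.75 * log(1 - 4 * p / 3)
    dN <- corr(pN); dS <- corr(pS)
  } else {
    dN <- NA_real_; dS <- NA_real_
  }
  data.frame(N = N, S = S, Nd = Nd, Sd = Sd, pN = pN, pS = pS,
             dN = dN, dS = dS,
             omega = if (!is.na(dS) && dS > 0) dN / dS else NA_real_,
             n_codons = length(ca))
}

#' Classify an omega estimate into a selection regime
#'
#' `purifying` if `omega < 1 - tau`, `neutral` if `|omega - 1| <= tau`,
#' `diversifying` if `omega > 1 + tau`, `undefined` for `NA`.
#'
#' @param omega dN/dS estimate(s).
#' @param tau half-width of the neutral band (default 0.1).
#' @return character vector of regimes.
#' @export
selectionClass <- function(omega, tau = 0.1) {
  out <- rep("undefined", length(omega))
  ok <- !is.na(omega)
  out[ok & omega < 1 - tau] <- "purifying"
  out[ok & abs(omega - 1) <= tau] <- "neutral"
  out[ok & omega > 1 + tau] <- "diversifying"
  out
}
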