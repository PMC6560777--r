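HYDROPHOBIC_AA <- c("A", "I", "L", "M", "F", "V", "W")
SMALL_AA <- c("A", "G", "S")

cysPositions <- function(seq) {
  which(strsplit(seq, "", fixed = TRUE)[[1L]] == "C")
}

#' Heuristic signal-peptide prediction
#'
#' A deterministic rule-based stand-in for an external secretion predictor,
#' modelled on the canonical tripartite signal-peptide architecture. Within
#' the first 30 residues a sequence is called secreted iff
#' \enumerate{
#'   \item a positively charged n-region: at least one K or R in positions
#'     1-5;
#'   \item a hydrophobic h-region: a window of 8 consecutive residues
#'     starting in positions 6-18 (so contained in 6-25) with at least 6
#'     residues from \{A, I, L, M, F, V, W\};
#'   \item a c-region consistent with the (-3, -1) rule: small residues
#'     (A, G or S) at positions `cs - 3` and `cs - 1`, where the cleavage
#'     site `cs` is three residues after the first qualifying hydrophobic
#'     window ends.
#' }
#' Sequences shorter than 25 residues return `FALSE` (documented, not an
#' error).
#'
#' @param seq amino-acid sequence string.
#' @return logical.
#' @examples
#' predictSignalPeptide(paste0("MKRTQLLLLLLLLATA", strrep("G", 40)))
#' @export
predictSignalPeptide <- function(seq) {
  seq <- as.character(seq)
  n <- nchar(seq)
  if (n < 25L) return(FALSE)
  ch <- strsplit(substr(seq, 1L, min(n, 35L)), "", fixed = TRUE)[[1L]]
  if (!any(ch[1:5] %in% c("K", "R"))) return(FALSE)
  hyd <- ch %in% HYDROPHOBIC_AA
  for (w in 6:18) {
    if (sum(hyd[w:(w + 7L)]) >= 6L) {
      cs <- w + 8L + 3L               # first position after the window, +3
      if (cs > length(ch)) return(FALSE)
      return(ch[cs - 3L] %in% SMALL_AA && ch[cs - 1L] %in% SMALL_AA)
    }
  }
  FALSE
}

#' SSCP candidate filter
#'
#' A protein qualifies as a small secreted cysteine-rich protein candidate
#' iff its length is strictly below `maxLen` residues, its cysteine fraction
#' is at least `minCysFrac` (inclusive), and it is secreted (built-in
#' heuristic, or an external call when supplied). `X` residues never count
#' as cysteines.
#'
#' @param seq amino-acid sequence string.
#' @param id protein id carried into the record.
#' @param maxLen strict length bound (default 300).
#' @param minCysFrac inclusive cysteine-fraction bound (default 0.05).
#' @param secreted optional externally supplied secretion call
#'   (TRUE/FALSE); NULL uses [predictSignalPeptide()].
#' @return one-row data.frame (an SSCP record): `protein_id`, `length`,
#'   `n_cys`, `cys_fraction`, `secreted`, `secretion_source`, `pass`.
#' @export
sscpFilter <- function(seq, id = NA_character_, maxLen = 300L,
                       minCysFrac = 0.05, secreted = NULL) {
  seq <- as.character(seq)
  if (!nzchar(seq)) stop("empty sequence")
  len <- nchar(seq)
  nc <- length(cysPositions(seq))
  if (is.null(secreted) || is.na(secreted)) {
    sec <- predictSignalPeptide(seq)
    src <- "heuristic"
  } else {
    sec <- as.logical(secreted)
    src <- "external"
  }
  frac <- nc / len
  data.frame(protein_id = id, length = len, n_cys = nc,
             cys_fraction = frac, secreted = sec, secretion_source = src,
             pass = len < maxLen && frac >= minCysFrac && sec,
             stringsAsFactors = FALSE)
}

#' Class-II-type hydrophobin cysteine pattern
#'
#' TRUE iff the sequence has exactly eight cysteines of which the 2nd/3rd
#' and the 6th/7th are directly adjacent residues (the CC doublets of
#' class II hydrophobins).
#'
#' @param seq amino-acid sequence string.
#' @return logical.
#' @export
classifyHydrophobin <- function(seq) {
  cp <- cysPositions(as.character(seq))
  length(cp) == 8L && cp[3L] == cp[2L] + 1L && cp[7L] == cp[6L] + 1L
}

#' Cerato-platanin cysteine pattern
#'
#' TRUE iff the sequence has exactly four cysteines. (Confirmation by
#' homology search, as done for real censuses, is out of scope.)
#'
#' @param seq amino-acid sequence string.
#' @return logical.
#' @export
classifyCeratoplatanin <- function(seq) {
  length(cysPositions(as.character(seq))) == 4L
}

#' Cysteine spacing profile
#'
#' Residue gaps between consecutive cysteines, e.g. `"C-9-CC-8-C"`; emitted
#' for manual inspection of hydrophobin subtypes, which the classifier does
#' not distinguish.
#'
#' @param seq amino-acid sequence string.
#' @return character spacing profile ("" when no cysteine).
#' @export
cysSpacingProfile <- function(seq) {
  cp <- cysPositions(as.character(seq))
  if (!length(cp)) return("")
  gaps <- diff(cp) - 1L
  out <- "C"
  for (g in gaps) out <- paste0(out, if (g == 0L) "" else paste0("-", g, "-"),
                                "C")
  out
}

#' SSCP census of one or several proteomes
#'
#' Applies [sscpFilter()] to every protein and labels filter-passing
#' proteins with precedence hydrophobin > cerato-platanin > sscp (classes
#' are mutually exclusive and exhaust the pass set). External secretion
#' calls, when given, override the heuristic per protein.
#'
#' @param proteomes a [Proteome-class] or list of them.
#' @param maxLen,minCysFrac filter parameters.
#' @param secretionCalls named logical vector by protein id (see
#'   [readSecretionCalls()]).
#' @return list with `census` (data.frame: taxon, sscp, hydrophobin,
#'   ceratoplatanin) and `records` (per-protein data.frame with `label` in
#'   \{hydrophobin, ceratoplatanin, sscp, none\} and `spacing` for
#'   hydrophobins).
#' @export
sscpCensus <- function(proteomes, maxLen = 300L, minCysFrac = 0.05,
                       secretionCalls = NULL) {
  if (is(proteomes, "Proteome")) proteomes <- list(proteomes)
  recs <- list()
  for (p in proteomes) {
    seqs <- as.character(sequences(p))
    for (id in names(seqs)) {
      ext <- if (!is.null(secretionCalls) && id %in% names(secretionCalls))
        secretionCalls[[id]] else NULL
      r <- sscpFilter(seqs[[id]], id = id, maxLen = maxLen,
                      minCysFrac = minCysFrac, secreted = ext)
      r$taxon <- taxonIds(p)
      r$label <- if (!r$pass) "none"
        else if (classifyHydrophobin(seqs[[id]])) "hydrophobin"
        else if (classifyCeratoplatanin(seqs[[id]])) "ceratoplatanin"
        else "sscp"
      r$spacing <- if (r$label == "hydrophobin") cysSpacingProfile(seqs[[id]])
        else NA_character_
      recs[[length(recs) + 1L]] <- r
    }
  }
  records <- if (length(recs)) do.call(rbind, recs) else
    data.frame(protein_id = character(), length = integer(),
               n_cys = integer(), cys_fraction = numeric(),
               secreted = logical(), secretion_source = character(),
               pass = logical(), taxon = character(), label = character(),
               spacing = character(), stringsAsFactors = FALSE)
  census <- do.call(rbind, lapply(vapply(proteomes, taxonIds, ""),
                                  function(tx) {
    r <- records[records$taxon == tx, ]
    data.frame(taxon = tx,
               sscp = sum(r$label == "sscp"),
               hydrophobin = sum(r$label == "hydrophobin"),
               ceratoplatanin = sum(r$label == "ceratoplatanin"),
               stringsAsFactors = FALSE)
  }))
  list(census = census, records = records)
}
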