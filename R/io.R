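#' Read a proteome from an amino-acid FASTA file
#'
#' The token before the first whitespace in each header is the protein id.
#' Sequences are uppercased; duplicate ids and empty sequences are errors.
#'
#' @param path FASTA file.
#' @param taxon taxon id; defaults to the file name without extension.
#' @return a [Proteome-class].
#' @export
readProteome <- function(path, taxon = sub("\\.[^.]*$", "", basename(path))) {
  if (!file.exists(path)) stop("no such file: ", path)
  aa <- Biostrings::readAAStringSet(path)
  ids <- sub("\\s.*$", "", names(aa))
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop("duplicate protein id(s) in ", path, ": ", paste(dup, collapse = ", "))
  w <- Biostrings::width(aa)
  if (any(w == 0L))
    stop("empty sequence for id(s): ", paste(ids[w == 0L], collapse = ", "))
  seqs <- toupper(as.character(aa))
  names(seqs) <- ids
  Proteome(taxon, seqs)
}

#' Write a proteome to FASTA
#'
#' @param proteome a [Proteome-class].
#' @param path output file.
#' @param width line width for wrapping.
#' @return `path`, invisibly.
#' @export
writeProteome <- function(proteome, path, width = 60L) {
  Biostrings::writeXStringSet(sequences(proteome), filepath = path,
                              width = width)
  invisible(path)
}

#' Read ortholog clusters in OrthoMCL groups format
#'
#' Each line reads `clusterID: taxon|protein taxon|protein ...`. The
#' taxon/protein separator is configurable. A protein occurring in two
#' clusters, or a malformed line, is an error.
#'
#' @param path groups file.
#' @param sep taxon/protein separator (default `"|"`).
#' @param taxa optional full taxon set (adds all-zero columns for taxa with
#'   no clustered genes).
#' @return a [ClusterTable-class] with member lists.
#' @export
readGroups <- function(path, sep = "|", taxa = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  members <- vector("list", length(lines))
  ids <- character(length(lines))
  for (i in seq_along(lines)) {
    ln <- trimws(lines[[i]])
    m <- regmatches(ln, regexec("^([^:[:space:]]+):\\s*(.*)$", ln))[[1L]]
    if (length(m) != 3L)
      stop("malformed groups line ", i, ": ", lines[[i]])
    ids[[i]] <- m[[2L]]
    toks <- strsplit(trimws(m[[3L]]), "\\s+")[[1L]]
    toks <- toks[nzchar(toks)]
    if (!length(toks))
      stop("malformed groups line ", i, " (no members): ", lines[[i]])
    parts <- strsplit(toks, sep, fixed = TRUE)
    if (any(lengths(parts) != 2L))
      stop("malformed member token on line ", i, ": ",
           toks[lengths(parts) != 2L][1L])
    members[[i]] <- data.frame(taxon = vapply(parts, `[[`, "", 1L),
                               protein = vapply(parts, `[[`, "", 2L),
                               stringsAsFactors = FALSE)
  }
  if (anyDuplicated(ids))
    stop("duplicate cluster id(s): ", paste(unique(ids[duplicated(ids)]),
                                            collapse = ", "))
  names(members) <- ids
  ClusterTable(members = members, taxa = taxa)
}

#' Write a ClusterTable in OrthoMCL groups format
#'
#' Requires member lists (a counts-only table cannot be serialized to
#' groups format).
#'
#' @param table a [ClusterTable-class] with members.
#' @param path output file.
#' @param sep taxon/protein separator.
#' @return `path`, invisibly.
#' @export
writeGroups <- function(table, path, sep = "|") {
  mem <- clusterMembers(table)
  if (!length(mem) && nrow(clusterCounts(table)) > 0L)
    stop("table has no member lists; cannot write groups format")
  lines <- vapply(clusterIds(table), function(cid) {
    m <- mem[[cid]]
    paste0(cid, ": ", paste(paste(m$taxon, m$protein, sep = sep),
                            collapse = " "))
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read a gene coordinate map
#'
#' The dialect is a TSV with header lines `#chrom <id> <length>` declaring
#' chromosome lengths, followed by a header row and five columns
#' `gene_id`, `chrom`, `start`, `end`, `strand` (1-based inclusive
#' coordinates; strand is carried but unused by the analyses). Gene ordinals
#' along each chromosome are assigned by start position.
#'
#' @param path gene map TSV.
#' @param taxon taxon id; defaults to file name.
#' @return a [GeneMap-class].
#' @export
readGeneMap <- function(path, taxon = sub("\\.[^.]*$", "", basename(path))) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  hdr <- grepl("^#chrom\\s", lines)
  chrom <- do.call(rbind, strsplit(trimws(sub("^#chrom\\s+", "", lines[hdr])),
                                   "\\s+"))
  if (is.null(chrom) || !nrow(chrom))
    stop("no '#chrom <id> <length>' header lines in ", path)
  chromLengths <- stats::setNames(as.numeric(chrom[, 2L]), chrom[, 1L])
  body <- lines[!hdr & !grepl("^#", lines) & nzchar(lines)]
  df <- utils::read.table(text = body, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("gene_id", "chrom", "start", "end")
  if (!all(need %in% names(df)))
    stop("gene map must have columns gene_id, chrom, start, end; got: ",
         paste(names(df), collapse = ", "))
  unknown <- setdiff(unique(df$chrom), names(chromLengths))
  if (length(unknown))
    stop("loci on undeclared chromosome(s): ", paste(unknown, collapse = ", "))
  over <- df$end > chromLengths[df$chrom] | df$start < 1 | df$start > df$end
  if (any(over))
    stop("locus beyond chromosome bounds: ",
         paste(df$gene_id[over], collapse = ", "))
  GeneMap(taxon, df, chromLengths)
}

#' Write a gene map in the package TSV dialect
#'
#' @param genemap a [GeneMap-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeGeneMap <- function(genemap, path) {
  gr <- geneLoci(genemap)
  sl <- GenomeInfoDb::seqlengths(gr)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#chrom %s %d", names(sl), as.integer(sl)), con)
  df <- data.frame(gene_id = names(gr),
                   chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr),
                   end = GenomicRanges::end(gr),
                   strand = "+")
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a rooted dated tree from Newick
#'
#' Leaf labels are taxon ids and branch lengths are interpreted as million
#' years (Mya). The tree must be rooted, with unique leaf labels and finite
#' non-negative branch lengths. Missing internal node labels are filled in
#' (`N1`, `N2`, ...).
#'
#' @param path Newick file.
#' @param requireLengths error if branch lengths are absent (default TRUE).
#' @return an [ape::phylo] object.
#' @export
readNewick <- function(path, requireLengths = TRUE) {
  if (!file.exists(path)) stop("no such file: ", path)
  tr <- ape::read.tree(path)
  if (is.null(tr)) stop("could not parse Newick in ", path)
  validateTimeTree(tr, requireLengths = requireLengths)
}

#' Validate (and label) a dated tree
#'
#' @param tree an `ape::phylo`.
#' @param requireLengths error if branch lengths are absent.
#' @return the tree, with internal node labels ensured.
#' @export
validateTimeTree <- function(tree, requireLengths = TRUE) {
  if (!inherits(tree, "phylo")) stop("not a phylo object")
  if (!ape::is.rooted(tree)) stop("tree is not rooted (ambiguous Newick)")
  if (anyDuplicated(tree$tip.label))
    stop("duplicate leaf label(s): ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
               collapse = ", "))
  if (is.null(tree$edge.length)) {
    if (requireLengths) stop("tree has no branch lengths")
  } else if (any(!is.finite(tree$edge.length)) || any(tree$edge.length < 0)) {
    stop("branch lengths must be finite and >= 0")
  }
  if (is.null(tree$node.label) || any(!nzchar(tree$node.label)))
    tree <- ape::makeNodeLabel(tree, prefix = "N")
  if (anyDuplicated(c(tree$tip.label, tree$node.label)))
    stop("node labels collide with leaf labels")
  tree
}

#' Read a clade partition from TSV
#'
#' Columns: `taxon`, `clade`, optional `species` (defaults to taxon) and
#' optional logical `ingroup` (defaults to clade != "OUTGROUP").
#'
#' @param path TSV file.
#' @return a [CladePartition-class].
#' @export
readCladePartition <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (!all(c("taxon", "clade") %in% names(df)))
    stop("clade file needs columns taxon, clade")
  clades <- stats::setNames(df$clade, df$taxon)
  species <- if ("species" %in% names(df))
    stats::setNames(df$species, df$taxon) else NULL
  ingroup <- if ("ingroup" %in% names(df))
    df$taxon[as.logical(df$ingroup)] else NULL
  CladePartition(clades, ingroup = ingroup, species = species)
}

#' Read external secretion calls
#'
#' TSV with columns `protein_id` and `secreted` (TRUE/FALSE or 1/0); used to
#' override the built-in signal-peptide heuristic with results from an
#' external predictor.
#'
#' @param path TSV file.
#' @return named logical vector by protein id.
#' @export
readSecretionCalls <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (!all(c("protein_id", "secreted") %in% names(df)))
    stop("secretion calls need columns protein_id, secreted")
  stats::setNames(as.logical(df$secreted), df$protein_id)
}
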