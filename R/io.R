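# Readers and writers for the plain-text formats the pipeline touches:
# FASTA, metadata/fixture TSV, Newick, and square PHYLIP distance matrices.

#' Read DNA sequences from a FASTA file
#'
#' Parses a (possibly wrapped) multi-record FASTA file into a
#' \linkS4class{DNAStringSet}. The header token before the first whitespace
#' becomes the sequence id; the remainder of the header is preserved in
#' \code{mcols()$description} but never used as an identifier. Residues are
#' upper-cased and RNA \code{U} is mapped to \code{T}.
#'
#' @param path path to an existing FASTA file.
#' @param locus locus tag attached to every record ("ITS", "COI" or "other").
#' @param aligned logical; when \code{TRUE}, gap characters (\code{-}) are
#'   accepted (alignment FASTA). Unaligned records must be gap-free.
#' @return \code{DNAStringSet} named by id, with \code{mcols()} columns
#'   \code{locus} and \code{description}.
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">seqA here", "ACGT", ">seqB", "acgu"), fa)
#' readFastaDNA(fa)
#' @export
readFastaDNA <- function(path, locus = c("other", "ITS", "COI"),
                         aligned = FALSE) {
  locus <- match.arg(locus)
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  x <- tryCatch(Biostrings::readBStringSet(path),
                error = function(e) stop("cannot parse FASTA '", path, "': ",
                                         conditionMessage(e)))
  if (length(x) == 0) stop("FASTA file '", path, "' contains no sequences")
  headers <- names(x)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  if (any(!nzchar(ids))) stop("FASTA entry with empty id in '", path, "'")
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0) stop("duplicate sequence id '", dup[1], "' in '", path, "'")
  seqs <- chartr("u", "t", as.character(x))
  seqs <- chartr("U", "T", toupper(seqs))
  names(seqs) <- ids
  if (any(!nzchar(seqs))) stop("empty sequence for id '", ids[!nzchar(seqs)][1], "'")
  .check_iupac(seqs, allow_gap = aligned)
  out <- Biostrings::DNAStringSet(seqs)
  S4Vectors::mcols(out) <- S4Vectors::DataFrame(
    locus = rep(locus, length(out)), description = desc)
  out
}

#' Write DNA sequences to a FASTA file
#'
#' @param x a named \code{DNAStringSet} (or named character vector).
#' @param path output path.
#' @param width line width for sequence wrapping.
#' @return invisibly, \code{path}.
#' @export
writeFastaDNA <- function(x, path, width = 70) {
  if (is.character(x)) x <- Biostrings::DNAStringSet(x)
  if (is.null(names(x)) || any(!nzchar(names(x))))
    stop("all sequences must be named before writing FASTA")
  Biostrings::writeXStringSet(x, filepath = path, width = width)
  invisible(path)
}

#' Read a sequence metadata table
#'
#' Reads a tab-separated table with header columns \code{sequence_id},
#' \code{specimen_id}, \code{species} and \code{locus}, mapping each sequence
#' to its specimen, (morpho)species label and locus. Species labels may be
#' empty (unidentified material); sequence ids must be unique.
#'
#' @param path path to the TSV file.
#' @return data.frame with the four columns above.
#' @export
readMetadata <- function(path) {
  if (!file.exists(path)) stop("metadata file not found: ", path)
  tab <- read.delim(path, stringsAsFactors = FALSE, colClasses = "character",
                    na.strings = NULL)
  need <- c("sequence_id", "specimen_id", "species", "locus")
  missing <- setdiff(need, names(tab))
  if (length(missing) > 0)
    stop("metadata is missing column(s): ", paste(missing, collapse = ", "))
  dup <- tab$sequence_id[duplicated(tab$sequence_id)]
  if (length(dup) > 0)
    stop("duplicated sequence_id in metadata: '", dup[1], "'")
  tab$species[is.na(tab$species)] <- ""
  tab[, need]
}

#' Path to the packaged COI/ITS divergence table transcription
#'
#' @return path to the packaged TSV (38 species rows of maximum
#'   intra-specific and minimum inter-specific K2P divergence per locus).
#' @export
divergenceFixturePath <- function() {
  system.file("extdata", "published_divergences.tsv", package = "MycoBarcode",
              mustWork = TRUE)
}

#' Load the packaged per-species divergence table
#'
#' Reads the packaged transcription of the published per-species divergence
#' comparison: for each species (or species pair) the maximum intra-specific
#' and minimum inter-specific K2P divergence at COI and at ITS. Inter-specific
#' cells printed as a dash in the source (divergence beyond the 20% clustering
#' cutoff, hence never measured) are encoded \code{CAPPED} and surface here as
#' \code{NA} values with the matching \code{*_capped} flag set; they resolve
#' to the capped value 0.21 through \code{\link{applyCap}}. Intra-specific
#' \code{NA} cells mark rows whose sequences span different species.
#'
#' @param path path to a fixture TSV; defaults to the packaged table.
#' @return data.frame with columns \code{label}, \code{n}, numeric
#'   \code{coi_intra}, \code{coi_inter}, \code{its_intra}, \code{its_inter},
#'   logical \code{coi_inter_capped}, \code{its_inter_capped}, plus
#'   \code{source_better} (locus highlighted in the source, \code{NA} for
#'   mixed-species rows) and free-text \code{flags}.
#' @examples
#' fx <- loadDivergenceFixture()
#' nrow(fx)  # 38
#' max(fx$its_intra, na.rm = TRUE)  # 0.0747
#' @export
loadDivergenceFixture <- function(path = divergenceFixturePath()) {
  if (!file.exists(path)) stop("fixture file not found: ", path)
  raw <- read.delim(path, stringsAsFactors = FALSE, colClasses = "character",
                    na.strings = NULL, fill = TRUE)
  need <- c("label", "n", "coi_intra", "coi_inter", "its_intra", "its_inter")
  missing <- setdiff(need, names(raw))
  if (length(missing) > 0)
    stop("fixture is missing column(s): ", paste(missing, collapse = ", "))
  parse_cell <- function(v, col, capped_ok) {
    is_capped <- v == "CAPPED"
    if (any(is_capped) && !capped_ok)
      stop("CAPPED is not legal in intra-specific column '", col, "'")
    is_na <- v %in% c("NA", "N.A.", "")
    num <- suppressWarnings(as.numeric(v))
    num[is_capped | is_na] <- NA_real_
    bad <- which(!is_capped & !is_na & is.na(num))
    if (length(bad) > 0)
      stop("unparseable value '", v[bad[1]], "' in column '", col, "'")
    out_of_range <- which(!is.na(num) & (num < 0 | num > 1))
    if (length(out_of_range) > 0)
      stop("value ", num[out_of_range[1]], " in column '", col,
           "' is outside [0, 1]")
    list(value = num, capped = is_capped)
  }
  coi_intra <- parse_cell(raw$coi_intra, "coi_intra", capped_ok = FALSE)
  its_intra <- parse_cell(raw$its_intra, "its_intra", capped_ok = FALSE)
  coi_inter <- parse_cell(raw$coi_inter, "coi_inter", capped_ok = TRUE)
  its_inter <- parse_cell(raw$its_inter, "its_inter", capped_ok = TRUE)
  data.frame(
    label = raw$label,
    n = as.integer(raw$n),
    coi_intra = coi_intra$value,
    coi_inter = coi_inter$value,
    its_intra = its_intra$value,
    its_inter = its_inter$value,
    coi_inter_capped = coi_inter$capped,
    its_inter_capped = its_inter$capped,
    source_better = if ("source_better" %in% names(raw))
      ifelse(raw$source_better %in% c("COI", "ITS"), raw$source_better,
             NA_character_) else NA_character_,
    flags = if ("flags" %in% names(raw)) {
      f <- raw$flags; f[is.na(f)] <- ""; f
    } else "",
    stringsAsFactors = FALSE
  )
}

#' Write a phylogenetic tree as Newick
#'
#' Writes a standard Newick string with branch lengths, terminated by a
#' semicolon. Leaf labels must be present, unique, and free of Newick
#' metacharacters; branch lengths must be non-negative.
#'
#' @param tree an \code{ape} \code{phylo} object.
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
writeNewick <- function(tree, path) {
  if (!inherits(tree, "phylo")) stop("'tree' must be a phylo object")
  labs <- tree$tip.label
  if (is.null(labs) || any(is.na(labs)) || any(!nzchar(labs)))
    stop("every leaf must carry a non-empty label")
  if (anyDuplicated(labs)) stop("leaf labels must be unique")
  bad <- grepl("[][;,():]", labs)
  if (any(bad))
    stop("leaf label contains a Newick metacharacter: '", labs[bad][1], "'")
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  if (any(tree$edge.length < 0)) stop("branch lengths must be non-negative")
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Read a Newick tree
#'
#' @param path path to a Newick file.
#' @return an \code{ape} \code{phylo} object.
#' @export
readNewick <- function(path) {
  if (!file.exists(path)) stop("Newick file not found: ", path)
  tr <- ape::read.tree(path)
  if (is.null(tr)) stop("cannot parse Newick file: ", path)
  tr
}

#' Write a distance matrix in square PHYLIP format
#'
#' First line: the number of taxa. Each following line: the taxon name,
#' whitespace, and its full row of distances. Undefined entries are written
#' as \code{NA} (re-readable by \code{\link{readPhylipDist}}).
#'
#' @param x a \linkS4class{K2PMatrix} or a square numeric matrix with
#'   dimnames.
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
writePhylipDist <- function(x, path) {
  m <- if (is(x, "K2PMatrix")) distances(x) else x
  if (!is.matrix(m) || nrow(m) != ncol(m)) stop("'x' must be a square matrix")
  ids <- rownames(m)
  if (is.null(ids)) stop("matrix must carry taxon names as dimnames")
  if (any(grepl("\\s", ids))) stop("taxon names must not contain whitespace")
  lines <- c(as.character(nrow(m)),
             vapply(seq_len(nrow(m)), function(i) {
               paste(ids[i], paste(format(m[i, ], trim = TRUE, digits = 10),
                                   collapse = " "))
             }, character(1)))
  writeLines(lines, path)
  invisible(path)
}

#' Read a square PHYLIP distance matrix
#'
#' @param path path to a square PHYLIP file.
#' @return numeric matrix with taxon dimnames (\code{NA} for undefined).
#' @export
readPhylipDist <- function(path) {
  if (!file.exists(path)) stop("PHYLIP file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  n <- as.integer(trimws(lines[1]))
  if (is.na(n) || length(lines) != n + 1)
    stop("malformed square PHYLIP file: expected ", n, " rows")
  ids <- character(n)
  m <- matrix(NA_real_, n, n)
  for (i in seq_len(n)) {
    toks <- strsplit(trimws(lines[i + 1]), "\\s+")[[1]]
    if (length(toks) != n + 1)
      stop("row ", i, " has ", length(toks) - 1, " entries, expected ", n)
    ids[i] <- toks[1]
    m[i, ] <- suppressWarnings(as.numeric(toks[-1]))
  }
  dimnames(m) <- list(ids, ids)
  m
}
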