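# Locus-specific preprocessing: ITS motif trimming and 5.8S excision;
# COI intron localization/excision against an intron-free reference exon;
# degenerate-primer mapping and amplicon prediction.
#
# All coordinates are 1-based, fully closed intervals.

#' ITS trimming configuration
#'
#' The conserved motifs marking the 3' terminus of the SSU and the 5'
#' terminus of the LSU that flank the ITS region; trimming to them puts all
#' amplicons on common end points regardless of primer choice.
#'
#' @param start_motif non-degenerate DNA motif opening the region
#'   (default \code{"CATTA"}).
#' @param end_motif non-degenerate DNA motif closing the region
#'   (default \code{"GACCT"}).
#' @return list of class \code{its_trim_config}.
#' @export
itsTrimConfig <- function(start_motif = "CATTA", end_motif = "GACCT") {
  for (m in c(start_motif, end_motif)) {
    if (!nzchar(m)) stop("motifs must be non-empty")
    if (!all(strsplit(toupper(m), "")[[1]] %in% c("A", "C", "G", "T")))
      stop("motifs must be non-degenerate DNA: '", m, "'")
  }
  structure(list(start_motif = toupper(start_motif),
                 end_motif = toupper(end_motif)), class = "its_trim_config")
}

#' Trim ITS sequences to their conserved flanking motifs
#'
#' Returns the subsequence from the \emph{first} occurrence of the start
#' motif through the \emph{last} occurrence of the end motif, motifs
#' included. Idempotent: trimming an already-trimmed sequence is a no-op.
#'
#' @param records unaligned sequences (\code{DNAStringSet}, named character
#'   vector, or a single string).
#' @param config an \code{\link{itsTrimConfig}}.
#' @return trimmed sequences, same container/naming as supplied.
#' @examples
#' trimITS("GGATCATTAAAAAGACCTCAAA")  # "CATTAAAAAGACCT"
#' @export
trimITS <- function(records, config = itsTrimConfig()) {
  seqs <- .as_seq_chr(records)
  out <- vapply(seq_along(seqs), function(i) {
    s <- seqs[[i]]
    id <- if (!is.null(names(seqs))) names(seqs)[i] else i
    start <- regexpr(config$start_motif, s, fixed = TRUE)[1]
    if (start < 0)
      stop("start motif '", config$start_motif, "' absent in '", id, "'")
    ends <- gregexpr(config$end_motif, s, fixed = TRUE)[[1]]
    if (ends[1] < 0)
      stop("end motif '", config$end_motif, "' absent in '", id, "'")
    end <- ends[length(ends)] + nchar(config$end_motif) - 1L
    if (end < start + nchar(config$start_motif) - 1L)
      stop("last end motif precedes first start motif in '", id, "'")
    substr(s, start, end)
  }, character(1))
  names(out) <- names(seqs)
  if (is(records, "XStringSet")) Biostrings::DNAStringSet(out) else out
}

#' Excise the 5.8S gene from trimmed ITS sequences
#'
#' Concatenates ITS1 (positions 1..\code{its1_end}) and ITS2 (positions
#' \code{its2_start}..length), removing the highly conserved ~120 bp 5.8S
#' gene between them: its near-invariance would otherwise inflate apparent
#' similarity between unrelated ITS sequences. Coordinates come from
#' annotation (e.g. GenBank records) and are supplied per record.
#'
#' @param records trimmed ITS sequences.
#' @param its1_end last position of ITS1 (1-based, inclusive); recycled.
#' @param its2_start first position of ITS2; recycled.
#' @return excised sequences, same container/naming as supplied.
#' @export
excise58S <- function(records, its1_end, its2_start) {
  seqs <- .as_seq_chr(records)
  n <- length(seqs)
  its1_end <- rep_len(as.integer(its1_end), n)
  its2_start <- rep_len(as.integer(its2_start), n)
  out <- vapply(seq_len(n), function(i) {
    s <- seqs[[i]]
    id <- if (!is.null(names(seqs))) names(seqs)[i] else i
    L <- nchar(s)
    if (its1_end[i] < 1 || its2_start[i] > L || its1_end[i] >= its2_start[i])
      stop("invalid 5.8S coordinates (its1_end=", its1_end[i],
           ", its2_start=", its2_start[i], ", length=", L, ") for '", id, "'")
    paste0(substr(s, 1, its1_end[i]), substr(s, its2_start[i], L))
  }, character(1))
  names(out) <- names(seqs)
  if (is(records, "XStringSet")) Biostrings::DNAStringSet(out) else out
}

# All exact shared anchor_len-mers between query and reference as
# (ref_pos, q_pos) pairs, sorted by (ref_pos, q_pos).
.shared_anchors <- function(query, ref, anchor_len) {
  kmers_of <- function(s) {
    L <- nchar(s)
    if (L < anchor_len) return(character(0))
    starts <- seq_len(L - anchor_len + 1)
    substring(s, starts, starts + anchor_len - 1)
  }
  kq <- kmers_of(query)
  kr <- kmers_of(ref)
  ref_index <- split(seq_along(kr), kr)
  hit <- which(kq %in% names(ref_index))
  if (length(hit) == 0) return(NULL)
  rp <- unlist(ref_index[kq[hit]], use.names = FALSE)
  qp <- rep(hit, times = lengths(ref_index[kq[hit]]))
  ord <- order(rp, qp)
  list(ref_pos = rp[ord], q_pos = qp[ord])
}

#' Localize intron insertions in a COI query against a reference exon
#'
#' Anchor-and-chain localization: all exact \code{anchor_len}-mers shared by
#' query and reference become anchors; the maximal collinear subset is
#' chained by longest-increasing-subsequence on (reference position, query
#' position); each inter-anchor stretch of extra query bases of at least
#' \code{min_intron_len} is reported as an intron. The reported position is
#' the 1-based reference coordinate of the last aligned base before the
#' insertion (0 for an insertion before the first anchored base).
#'
#' @param query a single unaligned sequence (the putatively intron-bearing
#'   amplicon).
#' @param reference_exon a single intron-free coding sequence.
#' @param min_intron_len smallest reportable insertion (default 50 bases).
#' @param anchor_len exact-match seed length (default 12): long enough to
#'   avoid chance hits in a ~450 bp exon, short enough to survive ~5%
#'   query-reference divergence.
#' @return data.frame with columns \code{query_id}, \code{position} (on the
#'   reference), \code{length}, and \code{query_pos} (last aligned query
#'   base before the insertion, used by \code{\link{exciseIntrons}});
#'   sorted by position. Zero rows when no insertion is found.
#' @export
detectIntrons <- function(query, reference_exon, min_intron_len = 50,
                          anchor_len = 12) {
  qs <- .as_seq_chr(query)[1]
  rs <- unname(.as_seq_chr(reference_exon)[1])
  qid <- if (!is.null(names(qs))) names(qs) else "query"
  qs <- unname(qs)
  anchors <- .shared_anchors(qs, rs, anchor_len)
  if (is.null(anchors))
    stop("unalignable: query '", qid, "' shares no ", anchor_len,
         "-mers with the reference")
  chain <- chain_anchors_cpp(anchors$ref_pos, anchors$q_pos)
  rp <- anchors$ref_pos[chain]
  qp <- anchors$q_pos[chain]
  calls <- list()
  # insertion before the first anchored base
  lead_extra <- qp[1] - rp[1]
  if (lead_extra >= min_intron_len)
    calls[[length(calls) + 1]] <- data.frame(
      query_id = qid, position = 0L, length = as.integer(lead_extra),
      query_pos = 0L)
  if (length(rp) > 1) {
    dq <- diff(qp)
    dr <- diff(rp)
    extra <- dq - dr
    for (k in which(extra >= min_intron_len)) {
      calls[[length(calls) + 1]] <- data.frame(
        query_id = qid,
        position = as.integer(rp[k] + anchor_len - 1L),
        length = as.integer(extra[k]),
        query_pos = as.integer(qp[k] + anchor_len - 1L))
    }
  }
  # insertion after the last anchored base
  tail_extra <- (nchar(qs) - (qp[length(qp)] + anchor_len - 1L)) -
    (nchar(rs) - (rp[length(rp)] + anchor_len - 1L))
  if (tail_extra >= min_intron_len)
    calls[[length(calls) + 1]] <- data.frame(
      query_id = qid,
      position = as.integer(rp[length(rp)] + anchor_len - 1L),
      length = as.integer(tail_extra),
      query_pos = as.integer(qp[length(qp)] + anchor_len - 1L))
  if (length(calls) == 0)
    return(data.frame(query_id = character(0), position = integer(0),
                      length = integer(0), query_pos = integer(0)))
  out <- do.call(rbind, calls)
  out[order(out$position), , drop = FALSE]
}

#' Excise called introns from a query sequence
#'
#' Removes every called insertion from the query, using the query
#' coordinates recorded by \code{\link{detectIntrons}}.
#'
#' @param query the sequence the calls were made on.
#' @param calls data.frame from \code{\link{detectIntrons}}.
#' @return the query with all insertions removed (character, or
#'   \code{DNAStringSet} if the input was one).
#' @export
exciseIntrons <- function(query, calls) {
  qs <- .as_seq_chr(query)[1]
  qname <- names(qs)
  s <- unname(qs)
  if (nrow(calls) == 0) {
    return(if (is(query, "XStringSet"))
      Biostrings::DNAStringSet(setNames(s, qname)) else s)
  }
  if (!all(c("query_pos", "length") %in% names(calls)))
    stop("'calls' must carry query_pos and length (from detectIntrons)")
  calls <- calls[order(calls$query_pos), , drop = FALSE]
  starts <- calls$query_pos + 1L
  ends <- calls$query_pos + calls$length
  if (any(starts[-1] <= ends[-length(ends)]))
    stop("overlapping intron calls")
  if (ends[length(ends)] > nchar(s)) stop("intron call exceeds query length")
  keep <- rep(TRUE, nchar(s))
  for (k in seq_along(starts)) keep[starts[k]:ends[k]] <- FALSE
  out <- paste(strsplit(s, "", fixed = TRUE)[[1]][keep], collapse = "")
  if (is(query, "XStringSet"))
    Biostrings::DNAStringSet(setNames(out, qname)) else out
}

#' Write intron calls as TSV
#'
#' @param calls data.frame from \code{\link{detectIntrons}} (possibly
#'   row-bound over queries).
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
writeIntronCalls <- function(calls, path) {
  write.table(calls[, c("query_id", "position", "length")], path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Degeneracy of an IUPAC primer
#'
#' The number of distinct exact oligonucleotides a degenerate primer
#' encodes: the product over positions of the IUPAC class sizes.
#'
#' @param primer IUPAC DNA string.
#' @return integer degeneracy (>= 1; 1 iff non-degenerate).
#' @examples
#' primerDegeneracy("TGRTTAAATTCHACHAAYGC")  # 36
#' @export
primerDegeneracy <- function(primer) {
  chars <- strsplit(toupper(.as_seq_chr(primer)[1]), "", fixed = TRUE)[[1]]
  bad <- which(!(chars %in% names(.IUPAC_BASES)))
  if (length(bad) > 0)
    stop("invalid IUPAC symbol '", chars[bad[1]], "' at position ", bad[1])
  prod(nchar(.IUPAC_BASES[chars]))
}

#' Map a degenerate primer onto a template
#'
#' Forward primers are matched against the plus strand; reverse primers are
#' matched as their reverse complement against the plus strand (the
#' reverse-strand binding orientation). A primer symbol matches a template
#' symbol when their IUPAC classes intersect, allowing up to
#' \code{max_mismatches} exceptions. Hits report the 5'-most template
#' coordinate of the matched window, sorted by start then strand.
#'
#' @param primer IUPAC DNA string (5'->3').
#' @param template a single unaligned template sequence.
#' @param direction \code{"forward"} or \code{"reverse"}.
#' @param max_mismatches allowed mismatching positions (default 0).
#' @return data.frame with columns \code{start}, \code{strand}
#'   (\code{"+"}/\code{"-"}), \code{mismatches}.
#' @export
mapPrimer <- function(primer, template, direction = c("forward", "reverse"),
                      max_mismatches = 0) {
  direction <- match.arg(direction)
  p <- toupper(.as_seq_chr(primer)[1])
  t <- unname(.as_seq_chr(template)[1])
  .check_iupac(setNames(p, "primer"), what = "primer")
  .check_iupac(setNames(t, "template"), what = "template")
  if (nchar(p) > nchar(t)) stop("primer is longer than the template")
  probe <- if (direction == "reverse") .reverse_complement(p) else p
  strand <- if (direction == "reverse") "-" else "+"
  pc <- strsplit(probe, "", fixed = TRUE)[[1]]
  tc <- strsplit(t, "", fixed = TRUE)[[1]]
  lp <- length(pc)
  n_win <- length(tc) - lp + 1
  mm <- integer(n_win)
  for (k in seq_len(lp)) {
    pk <- .IUPAC_BASES[[pc[k]]]
    tk <- tc[k:(k + n_win - 1)]
    # permissive: match when the IUPAC classes intersect
    compatible <- vapply(.IUPAC_BASES[tk], function(cls) {
      any(strsplit(cls, "")[[1]] %in% strsplit(pk, "")[[1]])
    }, logical(1))
    mm <- mm + !compatible
  }
  hits <- which(mm <= max_mismatches)
  data.frame(start = hits, strand = rep(strand, length(hits)),
             mismatches = mm[hits])
}

#' Predict amplicon length from a primer pair's binding sites
#'
#' Both primers are included in the product:
#' length = (reverse window start + reverse primer length - 1) -
#' forward window start + 1.
#'
#' @param fwd_start 5'-most template coordinate of the forward primer hit.
#' @param rev_start 5'-most template coordinate of the reverse primer hit
#'   (its binding window on the plus strand).
#' @param rev_primer_len length of the reverse primer.
#' @return integer amplicon length.
#' @examples
#' predictAmplicon(70, 724, 21)  # 675
#' @export
predictAmplicon <- function(fwd_start, rev_start, rev_primer_len) {
  if (rev_start <= fwd_start)
    stop("reverse primer window must lie strictly downstream of the forward hit")
  as.integer(rev_start + rev_primer_len - 1 - fwd_start + 1)
}

#' Read a primer table
#'
#' TSV with columns \code{name}, \code{sequence}, \code{direction}
#' (forward/reverse), \code{start_position} (1-based coordinate on the
#' reference exon, or NA when unknown).
#'
#' @param path path to the TSV; defaults to the packaged COI primer panel.
#' @return data.frame of primers.
#' @export
readPrimerTable <- function(path = system.file("extdata", "coi_primers.tsv",
                                               package = "MycoBarcode",
                                               mustWork = TRUE)) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("name", "sequence", "direction", "start_position")
  missing <- setdiff(need, names(tab))
  if (length(missing) > 0)
    stop("primer table is missing column(s): ", paste(missing, collapse = ", "))
  if (!all(tab$direction %in% c("forward", "reverse")))
    stop("primer direction must be 'forward' or 'reverse'")
  if (any(nchar(tab$sequence) < 10))
    stop("primer sequences must be at least 10 bases")
  tab
}
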