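# Pairwise and progressive alignment. These stand in for the external
# aligners a bench workflow would call: a linear-gap Needleman-Wunsch
# (optionally with free terminal gaps, "overlap" mode, the contig-assembly
# semantics used for percent-identity clustering) and a progressive MSA
# guided by a neighbor-joining tree on pairwise identity distances.

#' Alignment scoring parameters
#'
#' @param match score for an identical residue pair (default +1).
#' @param mismatch score for a non-identical pair (default -1).
#' @param gap linear per-base gap penalty, negative (default -2).
#' @param terminal_gaps_free when \code{TRUE} (default), terminal gap runs
#'   score zero and the identity denominator is the doubly-occupied overlap
#'   region -- the semantics of a contig-assembly "minimum overlap" match.
#' @return list of class \code{alignment_params}.
#' @export
alignmentParams <- function(match = 1, mismatch = -1, gap = -2,
                            terminal_gaps_free = TRUE) {
  if (gap >= 0) stop("'gap' must be negative")
  if (match <= mismatch) stop("'match' must exceed 'mismatch'")
  structure(list(match = match, mismatch = mismatch, gap = gap,
                 terminal_gaps_free = terminal_gaps_free),
            class = "alignment_params")
}

#' Align two DNA sequences
#'
#' Optimal dynamic-programming alignment under a linear gap penalty. In
#' overlap mode (\code{terminal_gaps_free = TRUE}) terminal gaps score zero.
#' Percent identity is computed over the doubly-occupied overlap region:
#' columns match only when both residues are identical (degenerate symbols
#' never match unless identical), and internal gap columns inside the
#' overlap count against identity. Traceback ties prefer diagonal, then a
#' gap in the second sequence, then a gap in the first, so the alignment is
#' deterministic.
#'
#' @param a,b unaligned sequences (character, \code{DNAString}, or
#'   length-one \code{DNAStringSet}).
#' @param params an \code{\link{alignmentParams}} object.
#' @return list with \code{aligned_a}, \code{aligned_b} (equal-length gapped
#'   strings), \code{score}, \code{overlap_start}, \code{overlap_end},
#'   \code{overlap_len}, and \code{identity} in [0, 1].
#' @examples
#' alignPair("ACGTACGT", "ACGTCGT")$identity
#' @export
alignPair <- function(a, b, params = alignmentParams()) {
  sa <- unname(.as_seq_chr(a)[1])
  sb <- unname(.as_seq_chr(b)[1])
  if (!nzchar(sa) || !nzchar(sb)) stop("cannot align an empty sequence")
  res <- nw_align_cpp(sa, sb, params$match, params$mismatch, params$gap,
                      isTRUE(params$terminal_gaps_free))
  ca <- strsplit(res$aligned_a, "", fixed = TRUE)[[1]]
  cb <- strsplit(res$aligned_b, "", fixed = TRUE)[[1]]
  occ_a <- which(ca != "-")
  occ_b <- which(cb != "-")
  ov_start <- max(occ_a[1], occ_b[1])
  ov_end <- min(occ_a[length(occ_a)], occ_b[length(occ_b)])
  ov_len <- max(0L, ov_end - ov_start + 1L)
  ident <- if (ov_len > 0) {
    idx <- ov_start:ov_end
    sum(ca[idx] == cb[idx] & ca[idx] != "-") / ov_len
  } else 0
  list(aligned_a = res$aligned_a, aligned_b = res$aligned_b,
       score = res$score, overlap_start = ov_start, overlap_end = ov_end,
       overlap_len = ov_len, identity = ident)
}

# Merge two gapped profiles (named character vectors) by profile-profile DP.
.merge_profiles <- function(pa, pb, params) {
  res <- profile_align_cpp(unname(pa), unname(pb),
                           params$match, params$mismatch, params$gap)
  setNames(c(res$rows_a, res$rows_b), c(names(pa), names(pb)))
}

#' Progressive multiple sequence alignment
#'
#' Aligns a set of sequences progressively: pairwise identity distances
#' (1 - identity) feed a neighbor-joining guide tree, and profiles are merged
#' bottom-up by profile-profile dynamic programming with mean-pairwise
#' (sum-of-pairs averaged) column scoring and a flat gap-column penalty.
#' Degapping any output row returns the corresponding input sequence.
#'
#' @param records named \code{DNAStringSet} (or named character vector) of at
#'   least two unaligned sequences.
#' @param params an \code{\link{alignmentParams}} object; profile merges use
#'   its match/mismatch/gap scores.
#' @return gapped \code{DNAStringSet}, rows in input order, equal widths.
#' @export
progressiveMSA <- function(records, params = alignmentParams()) {
  seqs <- .as_seq_chr(records)
  if (is.null(names(seqs)) || any(!nzchar(names(seqs))))
    stop("records must be named")
  n <- length(seqs)
  if (n == 1) {
    warning("single record: returned unchanged")
    return(Biostrings::DNAStringSet(seqs))
  }
  if (n == 2) {
    pr <- alignPair(seqs[1], seqs[2], params)
    return(Biostrings::DNAStringSet(
      setNames(c(pr$aligned_a, pr$aligned_b), names(seqs))))
  }
  d <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d[i, j] <- d[j, i] <- 1 - alignPair(seqs[i], seqs[j], params)$identity
    }
  }
  guide <- njTree(d)
  # post-order merge over the guide tree
  edge <- guide$edge
  ntip <- length(guide$tip.label)
  children <- split(edge[, 2], edge[, 1])
  merge_node <- function(node) {
    if (node <= ntip) {
      lab <- guide$tip.label[node]
      return(setNames(seqs[lab], lab))
    }
    kids <- children[[as.character(node)]]
    prof <- merge_node(kids[1])
    for (k in kids[-1]) prof <- .merge_profiles(prof, merge_node(k), params)
    prof
  }
  aln <- merge_node(ntip + 1L)
  Biostrings::DNAStringSet(aln[names(seqs)])
}
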