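# K2P-corrected distances, distance matrices, neighbor-joining and
# reciprocal-monophyly assessment.

#' Kimura two-parameter distance between two aligned sequences
#'
#' Counts transitions (A<->G, C<->T) and transversions over the comparable
#' sites and applies the K2P correction
#' \eqn{d = -\frac{1}{2}\ln[(1 - 2P - Q)\sqrt{1 - 2Q}]}. Under pairwise
#' deletion (default) a column is comparable only when both sequences carry
#' an unambiguous A/C/G/T; gap and ambiguity columns are excluded. Under
#' complete deletion, columns are first dropped wherever \emph{any} sequence
#' passed via \code{exclude_cols} is gapped/ambiguous (used by
#' \code{\link{k2pMatrix}}). The distance is undefined (\code{NA}) when the
#' logarithm's argument is non-positive (substitution saturation) or when no
#' sites are comparable; callers decide whether to cap or drop such pairs.
#'
#' @param aligned_a,aligned_b equal-length gapped strings.
#' @return list with \code{P} (transition proportion), \code{Q}
#'   (transversion proportion), \code{sites} (compared sites), and \code{d}
#'   (distance, or \code{NA} when undefined).
#' @examples
#' k2pDistance("ACGTACGTAC", "ACGTACGTAT")$d
#' @export
k2pDistance <- function(aligned_a, aligned_b) {
  sa <- unname(.as_seq_chr(aligned_a)[1])
  sb <- unname(.as_seq_chr(aligned_b)[1])
  if (nchar(sa) != nchar(sb))
    stop("aligned sequences must have equal length (", nchar(sa), " vs ",
         nchar(sb), ")")
  ca <- strsplit(sa, "", fixed = TRUE)[[1]]
  cb <- strsplit(sb, "", fixed = TRUE)[[1]]
  .k2p_from_chars(ca, cb)
}

.k2p_from_chars <- function(ca, cb) {
  acgt <- c("A", "C", "G", "T")
  valid <- ca %in% acgt & cb %in% acgt
  sites <- sum(valid)
  if (sites == 0)
    return(list(P = NA_real_, Q = NA_real_, sites = 0L, d = NA_real_))
  va <- ca[valid]
  vb <- cb[valid]
  differ <- va != vb
  purine_a <- va %in% c("A", "G")
  purine_b <- vb %in% c("A", "G")
  ts <- sum(differ & (purine_a == purine_b))  # A<->G or C<->T
  tv <- sum(differ) - ts
  P <- ts / sites
  Q <- tv / sites
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  d <- if (w1 <= 0 || w2 <= 0) NA_real_ else -0.5 * log(w1 * sqrt(w2))
  list(P = P, Q = Q, sites = as.integer(sites), d = d)
}

#' K2P distance matrix from a multiple alignment
#'
#' Computes all pairwise K2P distances over an alignment. Undefined entries
#' (saturation or zero comparable sites) are preserved as \code{NA} and
#' listed by \code{\link{undefinedPairs}}.
#'
#' @param msa gapped \code{DNAStringSet} or named character vector; all rows
#'   must have equal width.
#' @param deletion \code{"pairwise"} (default): each pair uses the columns
#'   where both members are unambiguous; \code{"complete"}: columns with a
#'   gap or ambiguity in \emph{any} row are removed once for all pairs.
#' @return a \linkS4class{K2PMatrix}.
#' @export
k2pMatrix <- function(msa, deletion = c("pairwise", "complete")) {
  deletion <- match.arg(deletion)
  seqs <- .as_seq_chr(msa)
  if (length(seqs) < 2) stop("need at least 2 aligned sequences")
  if (is.null(names(seqs)) || any(!nzchar(names(seqs))))
    stop("alignment rows must be named")
  widths <- nchar(seqs)
  if (length(unique(widths)) != 1)
    stop("ragged alignment: row widths ", paste(unique(widths), collapse = ", "))
  chars <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
  if (deletion == "complete") {
    keep <- apply(chars, 2, function(col) all(col %in% c("A", "C", "G", "T")))
    chars <- chars[, keep, drop = FALSE]
  }
  n <- length(seqs)
  d <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d[i, j] <- d[j, i] <- .k2p_from_chars(chars[i, ], chars[j, ])$d
    }
  }
  new("K2PMatrix", ids = names(seqs), dist = d)
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei neighbor joining with the standard Q-criterion. Negative
#' estimated branch lengths are clamped to zero. Ties in the Q-criterion are
#' broken by the lexicographically smallest joined pair of representative
#' taxon labels, so the result is deterministic.
#'
#' @param x a \linkS4class{K2PMatrix} or a square symmetric numeric matrix
#'   with taxon dimnames; no undefined (\code{NA}) entries.
#' @return an unrooted \code{ape} \code{phylo} object.
#' @export
njTree <- function(x) {
  m <- if (is(x, "K2PMatrix")) distances(x) else x
  if (!is.matrix(m) || nrow(m) != ncol(m) || is.null(rownames(m)))
    stop("'x' must be a square matrix with taxon dimnames")
  if (anyNA(m))
    stop("distance matrix contains undefined entries; cap them (see ",
         "applyCap) or drop the offending taxa before tree building")
  n <- nrow(m)
  if (n < 2) stop("need at least 2 taxa")
  labels <- rownames(m)
  fmt <- function(x) formatC(x, format = "g", digits = 15)
  if (n == 2) {
    h <- m[1, 2] / 2
    return(ape::read.tree(text = paste0(
      "(", labels[1], ":", fmt(h), ",", labels[2], ":", fmt(h), ");")))
  }
  newick <- labels       # growing subtree strings
  reps <- labels         # representative (smallest) original label per cluster
  D <- m
  while (nrow(D) > 3) {
    k <- nrow(D)
    r <- rowSums(D)
    Q <- (k - 2) * D - outer(r, r, "+")
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q <= qmin + 1e-12 & upper.tri(Q), arr.ind = TRUE)
    if (nrow(cand) > 1) {
      key1 <- pmin(reps[cand[, 1]], reps[cand[, 2]])
      key2 <- pmax(reps[cand[, 1]], reps[cand[, 2]])
      cand <- cand[order(key1, key2)[1], , drop = FALSE]
    }
    i <- cand[1, 1]; j <- cand[1, 2]
    vi <- D[i, j] / 2 + (r[i] - r[j]) / (2 * (k - 2))
    vj <- D[i, j] - vi
    vi <- max(vi, 0); vj <- max(vj, 0)
    merged <- paste0("(", newick[i], ":", fmt(vi), ",",
                     newick[j], ":", fmt(vj), ")")
    rep_new <- min(reps[i], reps[j])
    dk <- pmax((D[i, ] + D[j, ] - D[i, j]) / 2, 0)
    keep <- setdiff(seq_len(k), c(i, j))
    D2 <- D[keep, keep, drop = FALSE]
    D2 <- rbind(cbind(D2, dk[keep]), c(dk[keep], 0))
    newick <- c(newick[keep], merged)
    reps <- c(reps[keep], rep_new)
    D <- D2
  }
  # final trichotomy
  l1 <- max((D[1, 2] + D[1, 3] - D[2, 3]) / 2, 0)
  l2 <- max((D[1, 2] + D[2, 3] - D[1, 3]) / 2, 0)
  l3 <- max((D[1, 3] + D[2, 3] - D[1, 2]) / 2, 0)
  txt <- paste0("(", newick[1], ":", fmt(l1), ",", newick[2], ":", fmt(l2),
                ",", newick[3], ":", fmt(l3), ");")
  ape::read.tree(text = txt)
}

#' Assess reciprocal monophyly of species on a tree
#'
#' For each species with two or more leaves, reports whether some edge of
#' the unrooted tree separates exactly that species' leaves from all others.
#' Species with a single leaf are monophyletic by convention.
#'
#' @param tree an \code{ape} \code{phylo} object.
#' @param labels named character vector mapping every leaf label to a
#'   species label.
#' @return named logical vector, one entry per species.
#' @export
speciesMonophyly <- function(tree, labels) {
  if (!inherits(tree, "phylo")) stop("'tree' must be a phylo object")
  tips <- tree$tip.label
  missing <- setdiff(tips, names(labels))
  if (length(missing) > 0)
    stop("unlabeled leaf: '", missing[1], "'")
  species <- labels[tips]
  # bipartition sides: every internal-node clade plus every singleton
  clades <- lapply(ape::prop.part(tree), function(idx) sort(tips[idx]))
  sides <- c(clades, as.list(tips))
  keys <- vapply(sides, paste, character(1), collapse = "\r")
  out <- logical(0)
  for (sp in unique(species)) {
    sp_tips <- sort(tips[species == sp])
    if (length(sp_tips) < 2) { out[sp] <- TRUE; next }
    key_set <- paste(sp_tips, collapse = "\r")
    key_comp <- paste(sort(setdiff(tips, sp_tips)), collapse = "\r")
    out[sp] <- key_set %in% keys || key_comp %in% keys
  }
  out
}
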