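#' Alignment groups from greedy percent-identity clustering
#'
#' Container for the partition of a sequence set into "alignment groups":
#' clusters within which every joined member aligned to a prior member at or
#' above the identity threshold over at least the minimum overlap, so that
#' homology assessment (and hence distance computation) is unambiguous.
#' Multi-member groups carry a progressive multiple alignment.
#'
#' @slot membership data.frame with columns \code{group_id},
#'   \code{sequence_id}, \code{join_identity}, \code{overlap_len}; one row
#'   per input sequence. \code{join_identity}/\code{overlap_len} are \code{NA}
#'   for the sequence that founded its group.
#' @slot msas named list of gapped \linkS4class{DNAStringSet} alignments,
#'   one per multi-member group.
#' @slot params list of the \code{\link{groupingParams}} used.
#'
#' @seealso \code{\link{buildGroups}}
#' @export
setClass("AlignmentGroups",
  representation(membership = "data.frame", msas = "list", params = "list"))

setValidity("AlignmentGroups", function(object) {
  m <- object@membership
  need <- c("group_id", "sequence_id", "join_identity", "overlap_len")
  if (!all(need %in% names(m)))
    return(paste("membership must have columns", paste(need, collapse = ", ")))
  if (anyDuplicated(m$sequence_id))
    return("membership is not a partition: duplicated sequence_id")
  if (!all(names(object@msas) %in% m$group_id))
    return("msas named for unknown group ids")
  TRUE
})

#' @describeIn AlignmentGroups number of groups
#' @param x,object an \code{AlignmentGroups} object
#' @export
nGroups <- function(x) length(unique(x@membership$group_id))

#' @describeIn AlignmentGroups group identifiers, in creation order
#' @export
groupIds <- function(x) unique(x@membership$group_id)

#' @describeIn AlignmentGroups sequence ids belonging to one group
#' @param group_id a single group identifier
#' @export
groupMembers <- function(x, group_id) {
  x@membership$sequence_id[x@membership$group_id == group_id]
}

#' @describeIn AlignmentGroups the multiple alignment of one group
#'   (\code{NULL} for singletons)
#' @export
groupMSA <- function(x, group_id) {
  if (group_id %in% names(x@msas)) x@msas[[group_id]] else NULL
}

#' @describeIn AlignmentGroups the membership table
#' @export
groupMembership <- function(x) x@membership

setMethod("show", "AlignmentGroups", function(object) {
  sizes <- table(object@membership$group_id)
  cat("AlignmentGroups with", length(sizes), "group(s) over",
      nrow(object@membership), "sequence(s)\n")
  cat("  min_identity:", object@params$min_identity,
      " min_overlap:", object@params$min_overlap, "\n")
  cat("  group sizes:", paste(sort(as.integer(sizes), decreasing = TRUE),
                              collapse = " "), "\n")
})

#' K2P-corrected pairwise distance matrix
#'
#' Symmetric matrix of Kimura two-parameter distances over a set of sequence
#' ids, with a zero diagonal. Entries where the K2P logarithm is undefined
#' (substitution saturation, or no comparable sites under pairwise deletion)
#' are stored as \code{NA} and listed by \code{\link{undefinedPairs}};
#' downstream code maps them to the capped divergence value rather than
#' silently replacing them.
#'
#' @slot ids character vector of sequence ids (row/column order).
#' @slot dist numeric matrix of distances; \code{NA} marks undefined entries.
#'
#' @seealso \code{\link{k2pMatrix}}, \code{\link{k2pDistance}}
#' @export
setClass("K2PMatrix", representation(ids = "character", dist = "matrix"))

setValidity("K2PMatrix", function(object) {
  d <- object@dist
  if (nrow(d) != ncol(d)) return("matrix must be square")
  if (length(object@ids) != nrow(d)) return("ids must match matrix dimension")
  if (!isTRUE(all.equal(d, t(d)))) return("matrix must be symmetric")
  if (any(diag(d) != 0)) return("diagonal must be exactly zero")
  if (any(d < 0, na.rm = TRUE)) return("distances must be non-negative")
  TRUE
})

#' @describeIn K2PMatrix the distance matrix with id dimnames
#' @param x,object a \code{K2PMatrix}
#' @export
distances <- function(x) {
  d <- x@dist
  dimnames(d) <- list(x@ids, x@ids)
  d
}

#' @describeIn K2PMatrix data.frame of id pairs whose distance is undefined
#' @export
undefinedPairs <- function(x) {
  idx <- which(is.na(x@dist) & upper.tri(x@dist), arr.ind = TRUE)
  data.frame(id_a = x@ids[idx[, 1]], id_b = x@ids[idx[, 2]],
             stringsAsFactors = FALSE)
}

setMethod("show", "K2PMatrix", function(object) {
  n_und <- sum(is.na(object@dist[upper.tri(object@dist)]))
  cat("K2PMatrix over", length(object@ids), "sequence(s);",
      n_und, "undefined pair(s)\n")
  if (length(object@ids) <= 6) print(round(distances(object), 4))
})
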