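# Greedy construction of "alignment groups": clusters of sequences mutually
# alignable at or above an identity threshold over a minimum overlap, within
# which homology assessment is unambiguous. Replaces the contig-assembly
# step of chromatogram software with an open, deterministic algorithm.

#' Grouping parameters
#'
#' @param min_identity minimum overlap-region identity for joining a group
#'   (default 0.80).
#' @param min_overlap minimum doubly-occupied overlap, in bases (default 100).
#' @param order_policy \code{"canonical"} (default): sequences are processed
#'   in descending length, ties by id, making the result a pure function of
#'   the input set; \code{"input"}: process in the given order, exposing the
#'   order-dependence inherent to greedy assembly.
#' @return list of class \code{grouping_params}.
#' @export
groupingParams <- function(min_identity = 0.80, min_overlap = 100,
                           order_policy = c("canonical", "input")) {
  if (min_identity <= 0 || min_identity > 1)
    stop("'min_identity' must be in (0, 1]")
  if (min_overlap < 1) stop("'min_overlap' must be >= 1")
  structure(list(min_identity = min_identity,
                 min_overlap = as.integer(min_overlap),
                 order_policy = match.arg(order_policy)),
            class = "grouping_params")
}

#' Build alignment groups by greedy percent-identity clustering
#'
#' Processes sequences one at a time. Each sequence is aligned in overlap
#' mode against every member of every existing group; it joins the group
#' holding the best-identity member among those with identity >=
#' \code{min_identity} and overlap >= \code{min_overlap} (single linkage
#' within the greedy pass), and otherwise founds a new group. Exact identity
#' ties go to the earlier-created group. Multi-member groups then receive a
#' progressive multiple alignment.
#'
#' @param records named \code{DNAStringSet} (or named character vector) of
#'   unaligned, preprocessed sequences.
#' @param params a \code{\link{groupingParams}} object.
#' @param aln_params an \code{\link{alignmentParams}} object used for the
#'   identity alignments and the per-group MSAs.
#' @return an \linkS4class{AlignmentGroups} object.
#' @examples
#' recs <- c(s1 = strrep("ACGT", 50), s2 = strrep("ACGT", 50))
#' nGroups(buildGroups(recs, groupingParams(min_overlap = 50)))
#' @export
buildGroups <- function(records, params = groupingParams(),
                        aln_params = alignmentParams()) {
  seqs <- .as_seq_chr(records)
  if (length(seqs) == 0) stop("no input sequences")
  if (is.null(names(seqs)) || any(!nzchar(names(seqs))))
    stop("records must be named")
  if (anyDuplicated(names(seqs)))
    stop("duplicate sequence id: '", names(seqs)[duplicated(names(seqs))][1], "'")
  ord <- if (params$order_policy == "canonical") {
    order(-nchar(seqs), names(seqs))
  } else {
    seq_along(seqs)
  }
  seqs <- seqs[ord]
  groups <- list()   # each: list(ids = chr, seqs = chr)
  rows <- vector("list", length(seqs))
  for (s in seq_along(seqs)) {
    id <- names(seqs)[s]
    best_group <- NA_integer_
    best_ident <- -Inf
    best_ov <- NA_integer_
    for (g in seq_along(groups)) {
      for (mem in groups[[g]]$seqs) {
        pr <- alignPair(seqs[[s]], mem, aln_params)
        if (pr$identity >= params$min_identity &&
            pr$overlap_len >= params$min_overlap &&
            pr$identity > best_ident) {
          best_group <- g
          best_ident <- pr$identity
          best_ov <- pr$overlap_len
        }
      }
    }
    if (is.na(best_group)) {
      groups[[length(groups) + 1]] <- list(ids = id, seqs = seqs[s])
      rows[[s]] <- data.frame(group_idx = length(groups), sequence_id = id,
                              join_identity = NA_real_,
                              overlap_len = NA_integer_)
    } else {
      groups[[best_group]]$ids <- c(groups[[best_group]]$ids, id)
      groups[[best_group]]$seqs <- c(groups[[best_group]]$seqs, seqs[s])
      rows[[s]] <- data.frame(group_idx = best_group, sequence_id = id,
                              join_identity = best_ident,
                              overlap_len = as.integer(best_ov))
    }
  }
  membership <- do.call(rbind, rows)
  membership$group_id <- sprintf("AG%03d", membership$group_idx)
  membership <- membership[order(membership$group_idx),
                           c("group_id", "sequence_id", "join_identity",
                             "overlap_len")]
  rownames(membership) <- NULL
  msas <- list()
  for (g in seq_along(groups)) {
    if (length(groups[[g]]$ids) >= 2) {
      msas[[sprintf("AG%03d", g)]] <- progressiveMSA(groups[[g]]$seqs,
                                                     aln_params)
    }
  }
  new("AlignmentGroups", membership = membership, msas = msas,
      params = unclass(params))
}

#' Sensitivity of the grouping to input order
#'
#' Greedy assembly is order-dependent in principle: a sequence eligible for
#' two groups lands in whichever existed first. This re-runs
#' \code{\link{buildGroups}} under random input orders and reports how often
#' the canonical partition is reproduced.
#'
#' @param records named sequences, as for \code{\link{buildGroups}}.
#' @param params a \code{\link{groupingParams}} object (the shuffled runs use
#'   \code{order_policy = "input"}).
#' @param n_shuffles number of random orders (>= 1).
#' @param seed integer seed for the shuffles.
#' @param aln_params an \code{\link{alignmentParams}} object.
#' @return list with \code{agreement} (fraction of shuffles matching the
#'   canonical partition), \code{n_shuffles}, and \code{partitions}, the
#'   distinct partitions observed (each a list of sorted member-id vectors).
#' @export
groupingOrderSensitivity <- function(records, params = groupingParams(),
                                     n_shuffles = 20, seed = 1,
                                     aln_params = alignmentParams()) {
  if (n_shuffles < 1) stop("'n_shuffles' must be >= 1")
  seqs <- .as_seq_chr(records)
  canon_params <- params
  canon_params$order_policy <- "canonical"
  shuffle_params <- params
  shuffle_params$order_policy <- "input"
  partition_of <- function(gr) {
    parts <- split(gr@membership$sequence_id, gr@membership$group_id)
    parts <- lapply(parts, sort)
    unname(parts[order(vapply(parts, `[`, character(1), 1))])
  }
  canon <- partition_of(buildGroups(seqs, canon_params, aln_params))
  .with_seed(seed, {
    seen <- list(canon)
    hits <- 0L
    for (k in seq_len(n_shuffles)) {
      perm <- sample(length(seqs))
      part <- partition_of(buildGroups(seqs[perm], shuffle_params, aln_params))
      if (identical(part, canon)) {
        hits <- hits + 1L
      } else if (!any(vapply(seen, identical, logical(1), part))) {
        seen <- c(seen, list(part))
      }
    }
    list(agreement = hits / n_shuffles, n_shuffles = as.integer(n_shuffles),
         partitions = seen)
  })
}
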