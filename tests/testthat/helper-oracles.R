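# Independent oracles and generators used across the suite. These are kept
# deliberately naive (enumeration, per-site loops, graph traversal) so they
# share no code path with the package implementations they check.

random_dna <- function(n, bases = c("A", "C", "G", "T")) {
  paste(sample(bases, n, replace = TRUE), collapse = "")
}

# Exhaustive alignment score by enumeration over all monotone matchings
# between positions of a and b. Matched pairs score match/mismatch; each
# unmatched position costs one gap, except that in overlap mode unmatched
# positions before the first / after the last matched position of their own
# sequence are terminal and free. Enumerates all sum_k C(la,k)*C(lb,k)
# matchings, so only usable for short sequences.
brute_align_score <- function(a, b, match = 1, mismatch = -1, gap = -2,
                              overlap = FALSE) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  la <- length(ca); lb <- length(cb)
  score_matching <- function(ia, ib) {
    k <- length(ia)
    s <- sum(ifelse(ca[ia] == cb[ib], match, mismatch))
    if (overlap) {
      # at each end only one sequence's overhang can sit outside the other
      # (terminal, free); the shorter overhang is forced into internal gaps
      if (k == 0) return(0)
      internal_a <- (ia[k] - ia[1] + 1) - k
      internal_b <- (ib[k] - ib[1] + 1) - k
      lead <- min(ia[1] - 1, ib[1] - 1)
      trail <- min(la - ia[k], lb - ib[k])
      s + gap * (internal_a + internal_b + lead + trail)
    } else {
      s + gap * ((la - k) + (lb - k))
    }
  }
  best <- score_matching(integer(0), integer(0))
  for (k in seq_len(min(la, lb))) {
    combs_a <- utils::combn(la, k, simplify = FALSE)
    combs_b <- utils::combn(lb, k, simplify = FALSE)
    for (ia in combs_a) {
      for (ib in combs_b) {
        s <- score_matching(ia, ib)
        if (s > best) best <- s
      }
    }
  }
  best
}

# Per-site K2P computation with explicit loops and the closed form.
brute_k2p <- function(a, b) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  stopifnot(length(ca) == length(cb))
  sites <- 0L; ts <- 0L; tv <- 0L
  for (i in seq_along(ca)) {
    x <- ca[i]; y <- cb[i]
    if (x %in% c("A", "C", "G", "T") && y %in% c("A", "C", "G", "T")) {
      sites <- sites + 1L
      if (x != y) {
        if ((x %in% c("A", "G")) == (y %in% c("A", "G"))) ts <- ts + 1L
        else tv <- tv + 1L
      }
    }
  }
  if (sites == 0) return(list(sites = 0L, d = NA_real_, p = NA_real_))
  P <- ts / sites; Q <- tv / sites
  w1 <- 1 - 2 * P - Q; w2 <- 1 - 2 * Q
  d <- if (w1 <= 0 || w2 <= 0) NA_real_ else -0.5 * log(w1 * sqrt(w2))
  list(sites = sites, d = d, p = (ts + tv) / sites, P = P, Q = Q)
}

# Brute-force degenerate primer scan: every window, both orientations,
# symbol-by-symbol IUPAC class intersection.
IUPAC <- list(A = "A", C = "C", G = "G", T = "T", R = c("A", "G"),
              Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
              K = c("G", "T"), M = c("A", "C"), B = c("C", "G", "T"),
              D = c("A", "G", "T"), H = c("A", "C", "T"),
              V = c("A", "C", "G"), N = c("A", "C", "G", "T"))

brute_primer_scan <- function(primer, template, direction, max_mismatches = 0) {
  revcomp <- function(s) {
    comp <- c(A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R", S = "S",
              W = "W", K = "M", M = "K", B = "V", D = "H", H = "D", V = "B",
              N = "N")
    paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
  }
  probe <- if (direction == "reverse") revcomp(primer) else primer
  pc <- strsplit(probe, "")[[1]]
  tc <- strsplit(template, "")[[1]]
  hits <- integer(0); mms <- integer(0)
  for (s in seq_len(length(tc) - length(pc) + 1)) {
    mm <- 0L
    for (k in seq_along(pc)) {
      if (!any(IUPAC[[pc[k]]] %in% IUPAC[[tc[s + k - 1]]])) mm <- mm + 1L
    }
    if (mm <= max_mismatches) { hits <- c(hits, s); mms <- c(mms, mm) }
  }
  data.frame(start = hits, mismatches = mms)
}

# Tip bipartition induced by removing one edge: BFS over the remaining
# edges from the child endpoint. Independent of ape's clade machinery.
brute_bipartitions <- function(tree) {
  edges <- tree$edge
  tips <- tree$tip.label
  ntip <- length(tips)
  adj <- list()
  for (r in seq_len(nrow(edges))) {
    u <- as.character(edges[r, 1]); v <- as.character(edges[r, 2])
    adj[[u]] <- c(adj[[u]], edges[r, 2])
    adj[[v]] <- c(adj[[v]], edges[r, 1])
  }
  lapply(seq_len(nrow(edges)), function(r) {
    u <- edges[r, 1]; v <- edges[r, 2]
    seen <- v; queue <- v
    while (length(queue) > 0) {
      node <- queue[1]; queue <- queue[-1]
      for (nb in adj[[as.character(node)]]) {
        if (!(nb %in% seen) && !(node == v && nb == u)) {
          # do not cross the removed edge
          if (!(node == v && nb == u)) {
            seen <- c(seen, nb); queue <- c(queue, nb)
          }
        }
      }
    }
    sort(tips[seen[seen <= ntip]])
  })
}

brute_monophyly <- function(tree, labels) {
  tips <- tree$tip.label
  sides <- brute_bipartitions(tree)
  keys <- vapply(sides, paste, character(1), collapse = "\r")
  comp_keys <- vapply(sides, function(s) paste(sort(setdiff(tips, s)),
                                               collapse = "\r"), character(1))
  species <- unique(labels[tips])
  out <- logical(0)
  for (sp in species) {
    sp_tips <- sort(tips[labels[tips] == sp])
    if (length(sp_tips) < 2) { out[sp] <- TRUE; next }
    key <- paste(sp_tips, collapse = "\r")
    out[sp] <- key %in% keys || key %in% comp_keys
  }
  out
}

# Random unrooted additive tree with strictly positive branch lengths,
# plus its exact leaf-to-leaf path-distance matrix.
random_additive_case <- function(n_leaves) {
  tr <- ape::rtree(n_leaves, rooted = FALSE,
                   br = function(n) stats::runif(n, 0.05, 1))
  dm <- ape::cophenetic.phylo(tr)
  dm <- dm[sort(rownames(dm)), sort(rownames(dm))]
  list(tree = tr, dist = dm)
}

# Insert blocks into a reference to build an intron-bearing query; returns
# the query and the expected calls (position = ref base 5' of insertion).
# The first inserted base is forced to differ from the next reference base:
# otherwise the insertion point is genuinely ambiguous (+k shifts of an
# insertion sharing a k-prefix with the downstream reference describe the
# same query string).
construct_intron_query <- function(ref, positions, lengths, anchor_len = 12) {
  stopifnot(all(diff(c(0, positions)) > 0))
  chars <- strsplit(ref, "")[[1]]
  kmers <- function(s) {
    starts <- seq_len(nchar(s) - anchor_len + 1)
    substring(s, starts, starts + anchor_len - 1)
  }
  ref_kmers <- kmers(ref)
  random_foreign <- function(n) {
    # reject insertions sharing an exact anchor-length word with the
    # reference: such a coincidence makes an alternative parse of the
    # constructed query equally valid
    repeat {
      s <- random_dna(n)
      if (n < anchor_len || !any(kmers(s) %in% ref_kmers)) return(s)
    }
  }
  pieces <- character(0)
  prev <- 0
  for (k in seq_along(positions)) {
    ins <- strsplit(random_foreign(lengths[k]), "")[[1]]
    if (positions[k] < length(chars))
      ins[1] <- sample(setdiff(c("A", "C", "G", "T"),
                               chars[positions[k] + 1]), 1)
    pieces <- c(pieces,
                paste(chars[(prev + 1):positions[k]], collapse = ""),
                paste(ins, collapse = ""))
    prev <- positions[k]
  }
  if (prev < length(chars))
    pieces <- c(pieces, paste(chars[(prev + 1):length(chars)], collapse = ""))
  list(query = paste(pieces, collapse = ""),
       expected = data.frame(position = positions, length = lengths))
}
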