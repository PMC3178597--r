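# Seeded generator for multi-species sequence datasets with a controlled
# barcode gap, plus the dummy-sequence perturbation experiment that probes
# whether greedy clustering co-locates a perturbed copy with its source.

#' Simulate a multi-species barcode dataset
#'
#' Star phylogenies at both levels: a uniform-random root sequence spawns
#' one ancestor per species by Jukes-Cantor substitution along a branch of
#' \code{(inter_div - intra_div) / 2} expected substitutions per site; each
#' sequence is its species ancestor evolved along a branch of
#' \code{intra_div / 2}, with optional single-base indels at
#' \code{indel_rate} per site (insertions and deletions equally likely).
#' With this calibration the expected path length between two conspecific
#' tips is exactly \code{intra_div} and between two heterospecific tips
#' exactly \code{inter_div}; K2P estimation recovers path lengths, so the
#' mean intra-/inter-specific K2P distances estimate the two parameters
#' directly.
#'
#' @param n_species number of species.
#' @param seqs_per_species sequences per species.
#' @param seq_length root sequence length (default 600).
#' @param intra_div expected conspecific divergence (substitutions/site).
#' @param inter_div expected heterospecific divergence; must exceed
#'   \code{intra_div} and stay below 0.75 (JC saturation).
#' @param indel_rate per-base probability of a single-base indel on each
#'   terminal branch (default 0).
#' @param seed integer seed; the same seed reproduces the dataset exactly.
#' @return list with \code{records} (named \code{DNAStringSet},
#'   ids \code{sp<POS>_<k>}) and \code{labels} (metadata data.frame with
#'   columns \code{sequence_id}, \code{specimen_id}, \code{species},
#'   \code{locus}).
#' @export
simulateSpeciesDataset <- function(n_species, seqs_per_species,
                                   seq_length = 600, intra_div = 0.01,
                                   inter_div = 0.10, indel_rate = 0,
                                   seed = 1) {
  if (n_species < 1 || seqs_per_species < 1) stop("counts must be >= 1")
  if (seq_length < 1) stop("'seq_length' must be >= 1")
  if (intra_div < 0 || inter_div <= intra_div || inter_div > 0.75)
    stop("need 0 <= intra_div < inter_div <= 0.75")
  if (indel_rate < 0 || indel_rate > 0.1)
    stop("'indel_rate' must be in [0, 0.1]")
  bases <- c("A", "C", "G", "T")
  # JC substitution along a branch of t expected substitutions per site
  evolve <- function(chars, t) {
    if (t <= 0) return(chars)
    p_change <- 0.75 * (1 - exp(-4 * t / 3))
    hit <- runif(length(chars)) < p_change
    if (any(hit)) {
      chars[hit] <- vapply(chars[hit], function(b) {
        sample(setdiff(bases, b), 1)
      }, character(1))
    }
    chars
  }
  indels <- function(chars, rate) {
    if (rate <= 0) return(chars)
    u <- runif(length(chars))
    del <- u < rate / 2
    ins <- u >= rate / 2 & u < rate
    out <- as.list(chars)
    out[del] <- list(character(0))
    for (i in which(ins)) out[[i]] <- c(chars[i], sample(bases, 1))
    unlist(out)
  }
  .with_seed(seed, {
    root <- sample(bases, seq_length, replace = TRUE)
    seqs <- character(0)
    meta <- list()
    for (s in seq_len(n_species)) {
      anc <- evolve(root, (inter_div - intra_div) / 2)
      sp <- sprintf("sp%02d", s)
      for (k in seq_len(seqs_per_species)) {
        chars <- indels(evolve(anc, intra_div / 2), indel_rate)
        id <- sprintf("%s_%d", sp, k)
        seqs[id] <- paste(chars, collapse = "")
        meta[[id]] <- data.frame(sequence_id = id,
                                 specimen_id = sprintf("%s_spec%d", sp, k),
                                 species = sp, locus = "ITS",
                                 stringsAsFactors = FALSE)
      }
    }
    list(records = Biostrings::DNAStringSet(seqs),
         labels = do.call(rbind, c(meta, list(make.row.names = FALSE))))
  })
}

#' Perturb a sequence by substitutions or gaps
#'
#' Generates a "dummy" copy of a base sequence at a stated divergence,
#' counted as edit operations relative to the base length:
#' \describe{
#'   \item{SUBS_RANDOM}{\code{round(divergence * L)} positions, drawn without
#'     replacement, substituted to a different base; length preserved.}
#'   \item{GAPS_RANDOM}{the same number of single-base insertions at random
#'     positions.}
#'   \item{GAPS_EVEN}{single-base insertions at fixed spacing
#'     \code{ceiling(1 / divergence)} -- divergence 0.125 inserts an extra
#'     base every 8th position.}
#'   \item{GAP_BLOCK}{one contiguous insertion of
#'     \code{round(divergence * L)} bases at a random position.}
#' }
#'
#' @param base a single sequence of length >= 50.
#' @param mode one of \code{"SUBS_RANDOM"}, \code{"GAPS_RANDOM"},
#'   \code{"GAPS_EVEN"}, \code{"GAP_BLOCK"}.
#' @param divergence fraction in [0, 0.5].
#' @param seed integer seed.
#' @return the perturbed sequence (character).
#' @export
perturbSequence <- function(base, mode = c("SUBS_RANDOM", "GAPS_RANDOM",
                                           "GAPS_EVEN", "GAP_BLOCK"),
                            divergence, seed = 1) {
  mode <- match.arg(mode)
  s <- unname(.as_seq_chr(base)[1])
  if (nchar(s) < 50) stop("base sequence must be at least 50 bases")
  if (divergence < 0 || divergence > 0.5)
    stop("'divergence' must be in [0, 0.5]")
  if (divergence == 0) return(s)
  bases <- c("A", "C", "G", "T")
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  L <- length(chars)
  m <- round(divergence * L)
  .with_seed(seed, {
    out <- switch(mode,
      SUBS_RANDOM = {
        pos <- sample(L, m)
        chars[pos] <- vapply(chars[pos], function(b) {
          sample(setdiff(bases, b), 1)
        }, character(1))
        chars
      },
      GAPS_RANDOM = {
        pos <- sort(sample(L, m))
        res <- as.list(chars)
        for (p in pos) res[[p]] <- c(res[[p]], sample(bases, 1))
        unlist(res)
      },
      GAPS_EVEN = {
        k <- ceiling(1 / divergence)
        pos <- seq(k, L, by = k)
        res <- as.list(chars)
        for (p in pos) res[[p]] <- c(res[[p]], sample(bases, 1))
        unlist(res)
      },
      GAP_BLOCK = {
        p <- sample(L, 1)
        append(chars, sample(bases, m, replace = TRUE), after = p)
      })
    paste(out, collapse = "")
  })
}

#' Clustering-robustness experiment with dummy sequences
#'
#' For each perturbation on the grid, appends a perturbed copy of the base
#' sequence to the dataset, re-runs \code{\link{buildGroups}}, and records
#' whether dummy and base land in the same alignment group. Fully seeded
#' and reproducible.
#'
#' @param records named sequences (the dataset).
#' @param base_id id of the sequence to perturb (must be present).
#' @param grid data.frame with columns \code{mode}, \code{divergence}, and
#'   optionally \code{seed} (default: row number).
#' @param params a \code{\link{groupingParams}} object.
#' @param aln_params an \code{\link{alignmentParams}} object.
#' @return data.frame with columns \code{mode}, \code{divergence},
#'   \code{co_clustered}, \code{group_id_base}, \code{group_id_dummy}.
#' @export
robustnessExperiment <- function(records, base_id, grid,
                                 params = groupingParams(),
                                 aln_params = alignmentParams()) {
  seqs <- .as_seq_chr(records)
  if (!base_id %in% names(seqs))
    stop("base sequence '", base_id, "' is not in the dataset")
  if (!all(c("mode", "divergence") %in% names(grid)))
    stop("'grid' must have columns mode and divergence")
  if (is.null(grid$seed)) grid$seed <- seq_len(nrow(grid))
  dummy_id <- paste0(base_id, "_dummy")
  out <- lapply(seq_len(nrow(grid)), function(r) {
    dummy <- perturbSequence(seqs[[base_id]], grid$mode[r],
                             grid$divergence[r], seed = grid$seed[r])
    augmented <- c(seqs, setNames(dummy, dummy_id))
    gr <- buildGroups(augmented, params, aln_params)
    mem <- gr@membership
    g_base <- mem$group_id[mem$sequence_id == base_id]
    g_dummy <- mem$group_id[mem$sequence_id == dummy_id]
    data.frame(mode = grid$mode[r], divergence = grid$divergence[r],
               co_clustered = g_base == g_dummy,
               group_id_base = g_base, group_id_dummy = g_dummy,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
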