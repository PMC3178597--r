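# Per-species intra-/inter-specific divergence statistics, the capping rule
# for extreme inter-specific divergences, gap ratios, and locus comparison.

#' Cap extreme inter-specific divergences
#'
#' Inter-specific divergences beyond the clustering cutoff are never actually
#' measured (such pairs fall into different alignment groups), so values
#' above the threshold -- and undefined (\code{NA}) K2P distances -- are
#' recorded as the cap value, a minimum estimate of divergence. The boundary
#' value equal to the threshold is returned unchanged (strictly-greater
#' rule). Idempotent and monotone non-decreasing.
#'
#' @param value numeric vector of divergences (proportions), or \code{NA}
#'   for undefined distances.
#' @param cap_threshold divergences strictly above this are capped
#'   (default 0.20).
#' @param cap_value the recorded minimum estimate (default 0.21).
#' @return numeric vector with capped entries replaced by \code{cap_value}.
#' @examples
#' applyCap(c(0.35, 0.15, 0.20, NA))  # 0.21 0.15 0.20 0.21
#' @export
applyCap <- function(value, cap_threshold = 0.20, cap_value = 0.21) {
  if (any(value < 0, na.rm = TRUE)) stop("divergences must be non-negative")
  ifelse(is.na(value) | value > cap_threshold, cap_value, value)
}

#' Per-species divergence statistics within alignment groups
#'
#' Distances are only meaningful within an alignment group (beyond it,
#' homology is ambiguous), so intra-specific statistics are taken over
#' conspecific pairs co-resident in a group, and the inter-specific minimum
#' is the smallest distance from any member of the species to any
#' heterospecific sequence sharing its group, capped by
#' \code{\link{applyCap}}. A species whose group(s) contain no
#' heterospecific sequence gets a capped inter-specific divergence and no
#' nearest neighbor: its closest non-conspecific lies beyond the clustering
#' cutoff. Conspecific pairs split across groups are simply not compared.
#'
#' @param groups an \linkS4class{AlignmentGroups} object.
#' @param labels named character vector mapping every sequence id to a
#'   species label.
#' @param locus locus tag recorded in the output rows.
#' @param cap_threshold,cap_value see \code{\link{applyCap}}.
#' @param deletion K2P deletion policy, see \code{\link{k2pMatrix}}.
#' @return data.frame with one row per species: \code{species}, \code{locus},
#'   \code{n}, \code{intra_max}, \code{intra_mean}, \code{intra_median}
#'   (\code{NA} when fewer than two conspecifics share a group),
#'   \code{inter_min} (capped value applied), \code{inter_capped} (logical),
#'   \code{nearest_neighbor} (species label or \code{NA}).
#' @export
speciesStats <- function(groups, labels, locus = "ITS",
                         cap_threshold = 0.20, cap_value = 0.21,
                         deletion = "pairwise") {
  stopifnot(is(groups, "AlignmentGroups"))
  mem <- groups@membership
  unlabeled <- setdiff(mem$sequence_id, names(labels))
  if (length(unlabeled) > 0)
    stop("unlabeled sequence: '", unlabeled[1], "'")
  sp_of <- labels[mem$sequence_id]
  names(sp_of) <- mem$sequence_id
  species_all <- unique(unname(sp_of))
  intra <- setNames(vector("list", length(species_all)), species_all)
  inter_best <- setNames(rep(NA_real_, length(species_all)), species_all)
  inter_nn <- setNames(rep(NA_character_, length(species_all)), species_all)
  inter_und <- setNames(rep(FALSE, length(species_all)), species_all)
  for (gid in groupIds(groups)) {
    ids <- groupMembers(groups, gid)
    if (length(ids) < 2) next
    msa <- groupMSA(groups, gid)
    dm <- distances(k2pMatrix(msa[ids], deletion = deletion))
    for (a in seq_len(length(ids) - 1)) {
      for (b in (a + 1):length(ids)) {
        d <- dm[ids[a], ids[b]]
        sa <- sp_of[[ids[a]]]
        sb <- sp_of[[ids[b]]]
        if (sa == sb) {
          if (!is.na(d)) intra[[sa]] <- c(intra[[sa]], d)
        } else {
          for (pair in list(c(sa, sb), c(sb, sa))) {
            s1 <- pair[1]; s2 <- pair[2]
            if (is.na(d)) {
              # undefined inter-specific distance: at least saturation-level
              if (is.na(inter_best[s1])) inter_und[s1] <- TRUE
            } else if (is.na(inter_best[s1]) || d < inter_best[s1]) {
              inter_best[s1] <- d
              inter_nn[s1] <- s2
              inter_und[s1] <- FALSE
            }
          }
        }
      }
    }
  }
  out <- lapply(species_all, function(sp) {
    dv <- intra[[sp]]
    has_inter <- !is.na(inter_best[sp]) || inter_und[sp]
    raw_inter <- inter_best[sp]  # NA when capped-by-construction or undefined
    data.frame(
      species = sp, locus = locus, n = sum(sp_of == sp),
      intra_max = if (length(dv) > 0) max(dv) else NA_real_,
      intra_mean = if (length(dv) > 0) mean(dv) else NA_real_,
      intra_median = if (length(dv) > 0) median(dv) else NA_real_,
      inter_min = unname(applyCap(raw_inter, cap_threshold, cap_value)),
      inter_capped = is.na(raw_inter) ||
        applyCap(raw_inter, cap_threshold, cap_value) != raw_inter,
      nearest_neighbor = if (has_inter && !inter_und[sp]) unname(inter_nn[sp])
        else NA_character_,
      stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  res[order(res$species), , drop = FALSE]
}

#' Compare two loci by their barcode-gap ratios
#'
#' For each species present at both loci, computes the ratio of maximum
#' intra-specific to minimum inter-specific divergence (0 when the
#' intra-specific maximum is 0; \code{Inf} when the inter-specific minimum is
#' 0 with positive intra). The better locus is the one with the strictly
#' smaller intra:inter ratio; equal ratios (including both zero) tie. The
#' reciprocal inter:intra ratio is reported too: a usable barcode requires it
#' to exceed one.
#'
#' @param rows_a,rows_b data.frames from \code{\link{speciesStats}} (or rows
#'   with columns \code{species}, \code{locus}, \code{intra_max},
#'   \code{inter_min}), one per locus.
#' @return data.frame with per-species ratios for both loci
#'   (\code{ratio_<locus>} = intra/inter, \code{gap_<locus>} = inter/intra)
#'   and \code{better_locus} (a locus tag or \code{"TIE"}). Species missing
#'   from one locus are skipped with a warning.
#' @export
compareLoci <- function(rows_a, rows_b) {
  locus_a <- rows_a$locus[1]
  locus_b <- rows_b$locus[1]
  common <- intersect(rows_a$species, rows_b$species)
  skipped <- setdiff(union(rows_a$species, rows_b$species), common)
  if (length(skipped) > 0)
    warning("species missing at one locus skipped: ",
            paste(skipped, collapse = ", "))
  ra <- rows_a[match(common, rows_a$species), ]
  rb <- rows_b[match(common, rows_b$species), ]
  ratio <- function(intra, inter) {
    ifelse(is.na(intra) | intra == 0, 0,
           ifelse(inter == 0, Inf, intra / inter))
  }
  gap <- function(intra, inter) {
    ifelse(is.na(intra) | intra == 0, Inf,
           ifelse(inter == 0, 0, inter / intra))
  }
  r_a <- ratio(ra$intra_max, ra$inter_min)
  r_b <- ratio(rb$intra_max, rb$inter_min)
  better <- ifelse(r_a < r_b, locus_a, ifelse(r_b < r_a, locus_b, "TIE"))
  out <- data.frame(species = common, r_a, r_b,
                    gap_a = gap(ra$intra_max, ra$inter_min),
                    gap_b = gap(rb$intra_max, rb$inter_min),
                    better_locus = better, stringsAsFactors = FALSE)
  names(out)[2:5] <- c(paste0("ratio_", locus_a), paste0("ratio_", locus_b),
                       paste0("gap_", locus_a), paste0("gap_", locus_b))
  out
}

#' Summarize per-species divergence rows for one locus
#'
#' Extremes and moments of the intra- and inter-specific divergence columns:
#' the maximum of the per-species intra-specific maxima (\code{NA} rows
#' excluded), the minimum of the per-species inter-specific minima with
#' capped entries excluded (they are bounds, not measurements), and
#' mean/SE/median of both columns with capped entries entering the moments
#' at the cap value. SE is the sample standard deviation over species rows
#' divided by the square root of the row count.
#'
#' @param rows data.frame with columns \code{intra_max}, \code{inter_min},
#'   \code{inter_capped} (from \code{\link{speciesStats}} or
#'   \code{\link{fixtureToDivergenceRows}}).
#' @return one-row data.frame: \code{n_species}, \code{intra_max_max},
#'   \code{intra_mean}, \code{intra_se}, \code{intra_median},
#'   \code{inter_min_min}, \code{inter_mean}, \code{inter_se},
#'   \code{inter_median}, \code{n_capped}.
#' @examples
#' fx <- fixtureToDivergenceRows(loadDivergenceFixture())
#' summaryReport(fx$ITS)$intra_max_max  # 0.0747
#' @export
summaryReport <- function(rows) {
  if (nrow(rows) < 1) stop("need at least one row")
  intra <- rows$intra_max[!is.na(rows$intra_max)]
  inter <- rows$inter_min
  capped <- rows$inter_capped
  measured_inter <- inter[!capped & !is.na(inter)]
  mom <- function(x) {
    if (length(x) == 0)
      return(c(mean = NA_real_, se = NA_real_, median = NA_real_))
    c(mean = mean(x),
      se = if (length(x) > 1) sd(x) / sqrt(length(x)) else NA_real_,
      median = median(x))
  }
  mi <- mom(intra)
  me <- mom(inter[!is.na(inter)])
  data.frame(
    n_species = nrow(rows),
    intra_max_max = if (length(intra) > 0) max(intra) else NA_real_,
    intra_mean = mi[["mean"]], intra_se = mi[["se"]],
    intra_median = mi[["median"]],
    inter_min_min = if (length(measured_inter) > 0) min(measured_inter)
      else NA_real_,
    inter_mean = me[["mean"]], inter_se = me[["se"]],
    inter_median = me[["median"]],
    n_capped = sum(capped, na.rm = TRUE))
}

#' Convert the packaged divergence table to per-locus divergence rows
#'
#' Reshapes the fixture (one row per species with both loci side by side)
#' into the per-locus schema of \code{\link{speciesStats}}, resolving capped
#' cells to the cap value.
#'
#' @param fixture data.frame from \code{\link{loadDivergenceFixture}}.
#' @param cap_value value capped cells resolve to (default 0.21).
#' @return named list with elements \code{COI} and \code{ITS}, each a
#'   data.frame with columns \code{species}, \code{locus}, \code{n},
#'   \code{intra_max}, \code{inter_min}, \code{inter_capped}.
#' @export
fixtureToDivergenceRows <- function(fixture, cap_value = 0.21) {
  one <- function(locus, intra, inter, capped) {
    data.frame(species = fixture$label, locus = locus, n = fixture$n,
               intra_max = intra,
               inter_min = ifelse(capped, cap_value, inter),
               inter_capped = capped, stringsAsFactors = FALSE)
  }
  list(COI = one("COI", fixture$coi_intra, fixture$coi_inter,
                 fixture$coi_inter_capped),
       ITS = one("ITS", fixture$its_intra, fixture$its_inter,
                 fixture$its_inter_capped))
}
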