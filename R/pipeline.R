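# End-to-end orchestration: preprocess -> group -> align -> distances ->
# trees -> per-species statistics -> locus comparison -> summary, with all
# intermediate artifacts written as plain-text files and a run log.

#' Pipeline configuration
#'
#' Collects paths and stage parameters. Defaults match the individual stage
#' constructors. The configuration round-trips through a YAML file via
#' \code{\link{readPipelineConfig}} / \code{\link{writePipelineConfig}}.
#'
#' @param its_fasta,coi_fasta paths to per-locus FASTA files (either may be
#'   \code{NULL}, not both).
#' @param metadata path to the metadata TSV (see \code{\link{readMetadata}}).
#' @param output_dir directory for all outputs (created if absent).
#' @param reference_exon optional path to an intron-free COI reference exon
#'   FASTA; when given, introns are located and excised from COI queries.
#' @param trim_its trim ITS records to the conserved flanking motifs.
#' @param its58s optional path to a 5.8S locator TSV with columns
#'   \code{sequence_id}, \code{its1_end}, \code{its2_start}; when given, the
#'   5.8S region is excised from (trimmed) ITS records.
#' @param min_identity,min_overlap grouping thresholds
#'   (see \code{\link{groupingParams}}).
#' @param match,mismatch,gap alignment scores
#'   (see \code{\link{alignmentParams}}).
#' @param cap_threshold,cap_value capping rule (see \code{\link{applyCap}}).
#' @param seed integer seed recorded in the log (the pipeline itself is
#'   deterministic under canonical ordering).
#' @return list of class \code{pipeline_config}.
#' @export
pipelineConfig <- function(its_fasta = NULL, coi_fasta = NULL, metadata,
                           output_dir, reference_exon = NULL,
                           trim_its = FALSE, its58s = NULL,
                           min_identity = 0.80, min_overlap = 100,
                           match = 1, mismatch = -1, gap = -2,
                           cap_threshold = 0.20, cap_value = 0.21,
                           seed = 1) {
  structure(list(its_fasta = its_fasta, coi_fasta = coi_fasta,
                 metadata = metadata, output_dir = output_dir,
                 reference_exon = reference_exon, trim_its = trim_its,
                 its58s = its58s, min_identity = min_identity,
                 min_overlap = min_overlap, match = match,
                 mismatch = mismatch, gap = gap,
                 cap_threshold = cap_threshold, cap_value = cap_value,
                 seed = seed),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Unknown keys are rejected; missing keys take the
#' \code{\link{pipelineConfig}} defaults.
#'
#' @param path path to a YAML file.
#' @return list of class \code{pipeline_config}.
#' @export
readPipelineConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  vals <- yaml::read_yaml(path)
  known <- names(formals(pipelineConfig))
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0)
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  do.call(pipelineConfig, vals)
}

#' Write a pipeline configuration as YAML
#'
#' @param config a \code{\link{pipelineConfig}} object.
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
writePipelineConfig <- function(config, path) {
  yaml::write_yaml(Filter(Negate(is.null), unclass(config)), path)
  invisible(path)
}

.log_line <- function(con, level, ...) {
  msg <- paste0("[", level, "] ", ...)
  writeLines(msg, con)
  message(msg)
}

#' Run the full barcode evaluation pipeline
#'
#' Executes preprocessing, grouping, per-group alignment, K2P distance
#' matrices, neighbor-joining trees, per-species divergence statistics,
#' locus comparison (when both loci are supplied), and the per-locus
#' summary. All outputs are plain text under \code{config$output_dir}; a run
#' log records parameters, seed, package version, every capping event, and
#' every undefined-distance event.
#'
#' @param config a \code{\link{pipelineConfig}} object.
#' @return (invisibly) list with \code{status} -- 0 on success, 1 on input
#'   validation failure, 2 on computation failure -- plus \code{files}
#'   (paths written) and \code{stats} (per-locus species statistics).
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  fail <- function(status, msg) {
    message("[ERROR] ", msg)
    invisible(list(status = status, files = character(0), stats = NULL))
  }
  # --- validation (status 1) ---
  if (is.null(config$its_fasta) && is.null(config$coi_fasta))
    return(fail(1, "no input FASTA configured"))
  for (p in c(config$its_fasta, config$coi_fasta, config$metadata,
              config$reference_exon, config$its58s)) {
    if (!is.null(p) && !file.exists(p))
      return(fail(1, paste0("input file not found: ", p)))
  }
  meta <- tryCatch(readMetadata(config$metadata),
                   error = function(e) e)
  if (inherits(meta, "error"))
    return(fail(1, conditionMessage(meta)))
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(config$output_dir, "run.log")
  con <- file(log_path, open = "wt")
  on.exit(close(con), add = TRUE)
  .log_line(con, "INFO", "MycoBarcode ",
            as.character(utils::packageVersion("MycoBarcode")),
            " | R ", getRversion())
  .log_line(con, "INFO", "params: min_identity=", config$min_identity,
            " min_overlap=", config$min_overlap, " match=", config$match,
            " mismatch=", config$mismatch, " gap=", config$gap,
            " cap=", config$cap_threshold, "->", config$cap_value,
            " seed=", config$seed)
  res <- tryCatch({
    aln_params <- alignmentParams(config$match, config$mismatch, config$gap)
    grp_params <- groupingParams(config$min_identity, config$min_overlap)
    files <- character(0)
    stats <- list()
    loci <- c(if (!is.null(config$its_fasta)) "ITS",
              if (!is.null(config$coi_fasta)) "COI")
    for (locus in loci) {
      fasta <- if (locus == "ITS") config$its_fasta else config$coi_fasta
      recs <- readFastaDNA(fasta, locus = locus)
      missing_meta <- setdiff(names(recs), meta$sequence_id)
      if (length(missing_meta) > 0)
        stop("sequence '", missing_meta[1], "' has no metadata row")
      # preprocessing
      if (locus == "ITS" && isTRUE(config$trim_its)) {
        recs <- trimITS(recs)
        .log_line(con, "INFO", "ITS records trimmed to conserved motifs")
      }
      if (locus == "ITS" && !is.null(config$its58s)) {
        loc <- read.delim(config$its58s, stringsAsFactors = FALSE)
        idx <- match(names(recs), loc$sequence_id)
        if (anyNA(idx)) stop("5.8S locator misses sequence '",
                             names(recs)[is.na(idx)][1], "'")
        recs <- excise58S(recs, loc$its1_end[idx], loc$its2_start[idx])
        .log_line(con, "INFO", "5.8S region excised from ITS records")
      }
      if (locus == "COI" && !is.null(config$reference_exon)) {
        ref <- readFastaDNA(config$reference_exon)[1]
        all_calls <- list()
        seqs <- .as_seq_chr(recs)
        for (id in names(seqs)) {
          calls <- detectIntrons(setNames(seqs[id], id), ref)
          if (nrow(calls) > 0) {
            .log_line(con, "WARN", "introns in '", id, "' at ",
                      paste(calls$position, collapse = ","))
            seqs[id] <- exciseIntrons(seqs[id], calls)
            all_calls[[id]] <- calls
          }
        }
        recs <- Biostrings::DNAStringSet(seqs)
        if (length(all_calls) > 0) {
          f <- file.path(config$output_dir,
                         paste0(tolower(locus), "_introns.tsv"))
          writeIntronCalls(do.call(rbind, all_calls), f)
          files <- c(files, f)
        }
      }
      # grouping + per-group artifacts
      groups <- buildGroups(recs, grp_params, aln_params)
      f <- file.path(config$output_dir, paste0(tolower(locus), "_groups.tsv"))
      write.table(groupMembership(groups), f, sep = "\t", quote = FALSE,
                  row.names = FALSE)
      files <- c(files, f)
      labels <- setNames(meta$species, meta$sequence_id)
      mono_rows <- list()
      for (gid in groupIds(groups)) {
        msa <- groupMSA(groups, gid)
        if (is.null(msa)) next
        base <- file.path(config$output_dir,
                          paste0(tolower(locus), "_", gid))
        writeFastaDNA(msa, paste0(base, ".aln.fasta"))
        dm <- k2pMatrix(msa)
        writePhylipDist(dm, paste0(base, ".phylip"))
        files <- c(files, paste0(base, ".aln.fasta"), paste0(base, ".phylip"))
        und <- undefinedPairs(dm)
        if (nrow(und) > 0)
          .log_line(con, "WARN", "undefined K2P distance for ",
                    nrow(und), " pair(s) in ", gid, " (", locus, ")")
        if (length(groupMembers(groups, gid)) >= 3 && nrow(und) == 0) {
          tr <- njTree(dm)
          writeNewick(tr, paste0(base, ".nwk"))
          files <- c(files, paste0(base, ".nwk"))
          mono <- speciesMonophyly(tr, labels)
          n_leaves <- table(labels[tr$tip.label])
          mono_rows[[gid]] <- data.frame(
            group_id = gid, species = names(mono),
            n_leaves = as.integer(n_leaves[names(mono)]),
            monophyletic = unname(mono), stringsAsFactors = FALSE)
        }
      }
      if (length(mono_rows) > 0) {
        f <- file.path(config$output_dir,
                       paste0(tolower(locus), "_monophyly.tsv"))
        write.table(do.call(rbind, mono_rows), f, sep = "\t", quote = FALSE,
                    row.names = FALSE)
        files <- c(files, f)
      }
      st <- speciesStats(groups, labels, locus = locus,
                         cap_threshold = config$cap_threshold,
                         cap_value = config$cap_value)
      n_cap <- sum(st$inter_capped, na.rm = TRUE)
      if (n_cap > 0)
        .log_line(con, "WARN", n_cap, " species capped at ",
                  config$cap_value, " (", locus, ")")
      f <- file.path(config$output_dir,
                     paste0(tolower(locus), "_species_stats.tsv"))
      write.table(st, f, sep = "\t", quote = FALSE, row.names = FALSE)
      files <- c(files, f)
      f <- file.path(config$output_dir,
                     paste0(tolower(locus), "_summary.tsv"))
      write.table(summaryReport(st), f, sep = "\t", quote = FALSE,
                  row.names = FALSE)
      files <- c(files, f)
      stats[[locus]] <- st
    }
    if (length(stats) == 2) {
      cmp <- compareLoci(stats$COI, stats$ITS)
      f <- file.path(config$output_dir, "locus_comparison.tsv")
      write.table(cmp, f, sep = "\t", quote = FALSE, row.names = FALSE)
      files <- c(files, f)
    }
    .log_line(con, "INFO", "pipeline complete: ", length(files), " file(s)")
    list(status = 0, files = files, stats = stats)
  }, error = function(e) {
    .log_line(con, "ERROR", conditionMessage(e))
    list(status = 2, files = character(0), stats = NULL)
  })
  invisible(res)
}
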