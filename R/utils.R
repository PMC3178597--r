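# Internal helpers shared across modules.

.IUPAC_BASES <- c(
  A = "A", C = "C", G = "G", T = "T",
  R = "AG", Y = "CT", S = "CG", W = "AT", K = "GT", M = "AC",
  B = "CGT", D = "AGT", H = "ACT", V = "ACG", N = "ACGT"
)

# Coerce sequences to a named character vector of upper-case residues.
# Accepts character vectors, DNAString/BString, and XStringSet objects.
.as_seq_chr <- function(x) {
  if (is(x, "XStringSet")) {
    out <- as.character(x)
  } else if (is(x, "XString")) {
    out <- setNames(as.character(x), "seq1")
  } else if (is.character(x)) {
    out <- x
  } else {
    stop("cannot interpret object of class '", class(x)[1], "' as sequences")
  }
  toupper(out)
}

# Validate residues against the IUPAC DNA alphabet; gaps optional.
.check_iupac <- function(seqs, allow_gap = FALSE, what = "sequence") {
  alphabet <- names(.IUPAC_BASES)
  if (allow_gap) alphabet <- c(alphabet, "-")
  for (i in seq_along(seqs)) {
    chars <- strsplit(seqs[[i]], "", fixed = TRUE)[[1]]
    bad <- which(!(chars %in% alphabet))
    if (length(bad) > 0) {
      id <- if (!is.null(names(seqs))) names(seqs)[i] else i
      stop("non-IUPAC character '", chars[bad[1]], "' at position ", bad[1],
           " in ", what, " '", id, "'")
    }
  }
  invisible(TRUE)
}

.reverse_complement <- function(seq) {
  comp <- c(A = "T", C = "G", G = "C", T = "A",
            R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K",
            B = "V", D = "H", H = "D", V = "B", N = "N", `-` = "-")
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  paste(rev(unname(comp[chars])), collapse = "")
}

# Run code under a locally seeded RNG, restoring the caller's RNG state.
.with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

.stopifnot_scalar_id <- function(id) {
  if (!is.character(id) || length(id) != 1 || is.na(id) || !nzchar(id))
    stop("'id' must be a single non-empty string")
}
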