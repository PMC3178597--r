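# ITS trimming and 5.8S excision; intron detection/excision; primer tools.

test_that("ITS trimming spans first start motif to last end motif", {
  expect_equal(trimITS("GGATCATTAAAAAGACCTCAAA"), "CATTAAAAAGACCT")
  # last end motif wins
  expect_equal(trimITS("CATTAAGACCTGGACCT"), "CATTAAGACCTGGACCT")
  expect_error(trimITS("GGGGACCTAAA"), "start motif")
  expect_error(trimITS("GGCATTAAAA"), "end motif")
  expect_error(trimITS("GACCTTTTTCATTA"), "precedes")
})

test_that("ITS trimming is idempotent and container-preserving", {
  set.seed(31)
  for (i in 1:20) {
    s <- paste0(random_dna(sample(5:60, 1)), "CATTA",
                random_dna(sample(50:200, 1)), "GACCT",
                random_dna(sample(5:60, 1)))
    once <- trimITS(s)
    expect_equal(trimITS(once), once)
    expect_true(startsWith(once, "CATTA") && endsWith(once, "GACCT"))
  }
  x <- Biostrings::DNAStringSet(c(r1 = "GGATCATTAAAAAGACCTCAAA"))
  out <- trimITS(x)
  expect_s4_class(out, "DNAStringSet")
  expect_equal(names(out), "r1")
})

test_that("5.8S excision concatenates ITS1 and ITS2 with exact arithmetic", {
  set.seed(32)
  s <- random_dna(300)
  out <- excise58S(s, 100, 221)
  expect_equal(nchar(out), 180)
  expect_equal(out, paste0(substr(s, 1, 100), substr(s, 221, 300)))
  expect_error(excise58S(s, 0, 221), "invalid")
  expect_error(excise58S(s, 150, 120), "invalid")
  expect_error(excise58S(s, 100, 301), "invalid")
  for (i in 1:25) {
    L <- sample(150:400, 1)
    e1 <- sample(30:100, 1)
    s2 <- sample((e1 + 2):(L - 10), 1)
    x <- random_dna(L)
    expect_equal(nchar(excise58S(x, e1, s2)), e1 + (L - s2 + 1))
  }
})

test_that("intron detection localizes constructed insertions", {
  set.seed(33)
  ref <- random_dna(450)
  expect_equal(nrow(detectIntrons(ref, ref)), 0)
  case <- construct_intron_query(ref, 101, 1500)
  calls <- detectIntrons(case$query, ref)
  expect_equal(calls$position, 101L)
  expect_equal(calls$length, 1500L)
  # two insertions, mirroring plausible primer-region sites
  case2 <- construct_intron_query(ref, c(64, 160), c(200, 300))
  calls2 <- detectIntrons(case2$query, ref)
  expect_equal(calls2$position, c(64L, 160L))
  expect_equal(calls2$length, c(200L, 300L))
  expect_error(detectIntrons(random_dna(400), ref), "unalignable")
})

test_that("intron excision restores the reference and conserves length", {
  set.seed(34)
  ref <- random_dna(500)
  expect_equal(exciseIntrons(ref, detectIntrons(ref, ref)), ref)
  for (i in 1:15) {
    k <- sample(1:3, 1)
    pos <- sort(sample(seq(30, 470, by = 30), k))
    len <- sample(100:800, k, replace = TRUE)
    case <- construct_intron_query(ref, pos, len)
    calls <- detectIntrons(case$query, ref)
    expect_equal(calls$position, as.integer(pos))
    expect_equal(calls$length, as.integer(len))
    restored <- exciseIntrons(case$query, calls)
    expect_equal(restored, ref)
    expect_equal(nchar(case$query) - sum(len), nchar(restored))
  }
})

test_that("primer degeneracy is the product of IUPAC class sizes", {
  expect_equal(primerDegeneracy("ACGT"), 1)
  expect_equal(primerDegeneracy("TGRTTAAATTCHACHAAYGC"), 36)
  expect_equal(primerDegeneracy("GACGGCATTTTCWGTTCTTATTAG"), 2)
  expect_error(primerDegeneracy("ACXT"), "position 3")
  set.seed(35)
  for (i in 1:20) {
    p <- paste(sample(names(MycoBarcode:::.IUPAC_BASES), 15, replace = TRUE),
               collapse = "")
    expect_gte(primerDegeneracy(p), 1)
  }
  # degeneracy 1 iff non-degenerate
  expect_equal(primerDegeneracy("ACGTACGTAC"), 1)
  expect_gt(primerDegeneracy("ACGTACGTAN"), 1)
})

test_that("primer mapping matches a brute-force scan on both strands", {
  f <- mapPrimer("ACGT", "TTACGTTT", "forward")
  expect_equal(f$start, 3)
  expect_equal(f$strand, "+")
  r <- mapPrimer("ACGT", "TTACGTTT", "reverse")
  expect_equal(r$start, 3)  # revcomp(ACGT) = ACGT
  expect_equal(r$strand, "-")
  # IUPAC semantics
  hits <- mapPrimer("ARGT", "AAGTTAGGT", "forward")
  expect_equal(hits$start, c(1, 6))
  set.seed(36)
  for (i in 1:15) {
    primer <- paste(sample(names(IUPAC), sample(10:20, 1), replace = TRUE),
                    collapse = "")
    template <- random_dna(sample(200:600, 1))
    for (dir in c("forward", "reverse")) {
      mine <- mapPrimer(primer, template, dir, max_mismatches = 2)
      brute <- brute_primer_scan(primer, template, dir, max_mismatches = 2)
      expect_equal(mine$start, brute$start)
      expect_equal(mine$mismatches, brute$mismatches)
    }
  }
})

test_that("the packaged primer panel maps cleanly and amplicons add up", {
  primers <- readPrimerTable()
  expect_equal(nrow(primers), 17)
  expect_true(all(primers$direction %in% c("forward", "reverse")))
  degs <- vapply(primers$sequence, primerDegeneracy, numeric(1))
  expect_true(all(degs >= 1))
  expect_equal(unname(degs[primers$name == "5F"]), 36)
  # both primers are included in the amplicon
  expect_equal(predictAmplicon(1, 91, 10), 100L)
  fwd <- primers[primers$name == "11F", ]
  rev <- primers[primers$name == "2eR", ]
  expect_equal(predictAmplicon(fwd$start_position, rev$start_position,
                               nchar(rev$sequence)), 675L)
  expect_error(predictAmplicon(724, 70, 21), "downstream")
})
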