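# Capping rule, per-species statistics, locus comparison, summaries.

test_that("the capping rule is strict-greater, idempotent, and monotone", {
  expect_equal(applyCap(0.35), 0.21)
  expect_equal(applyCap(0.15), 0.15)
  expect_equal(applyCap(0.20), 0.20)   # boundary untouched
  expect_equal(applyCap(NA_real_), 0.21)  # undefined distances are capped
  expect_error(applyCap(-0.01), "non-negative")
  x <- c(0, 0.05, 0.2, 0.200001, 0.5, NA)
  expect_equal(applyCap(applyCap(x)), applyCap(x))
  xs <- sort(c(runif(50, 0, 0.4), 0.2))
  expect_true(all(diff(applyCap(xs)) >= 0))
})

test_that("species stats follow hand-enumerated distances in a mixed group", {
  # build a three-sequence group: A1,A2 conspecific, B1 the neighbor
  set.seed(71)
  base <- random_dna(200)
  mutate_at <- function(s, pos) {
    ch <- strsplit(s, "")[[1]]
    ch[pos] <- vapply(ch[pos], function(b) {
      sample(setdiff(c("A", "C", "G", "T"), b), 1)
    }, character(1))
    paste(ch, collapse = "")
  }
  recs <- c(A1 = base, A2 = mutate_at(base, 1:2), B1 = mutate_at(base, 50:61))
  g <- buildGroups(recs)
  expect_equal(nGroups(g), 1L)
  st <- speciesStats(g, c(A1 = "A", A2 = "A", B1 = "B"), locus = "ITS")
  msa <- groupMSA(g, groupIds(g)[1])
  d <- distances(k2pMatrix(msa))
  a_row <- st[st$species == "A", ]
  b_row <- st[st$species == "B", ]
  expect_equal(a_row$intra_max, d["A1", "A2"])
  expect_equal(a_row$inter_min, min(d["A1", "B1"], d["A2", "B1"]))
  expect_equal(a_row$nearest_neighbor, "B")
  expect_true(is.na(b_row$intra_max))   # single B sequence
  expect_equal(b_row$inter_min, min(d["A1", "B1"], d["A2", "B1"]))
  expect_false(any(st$inter_capped))
})

test_that("species alone in their group get a capped inter-specific divergence", {
  set.seed(72)
  s1 <- random_dna(200)
  s2 <- random_dna(200)   # unrelated: lands in its own group
  g <- buildGroups(c(A1 = s1, A2 = s1, B1 = s2))
  expect_equal(nGroups(g), 2L)
  st <- speciesStats(g, c(A1 = "A", A2 = "A", B1 = "B"))
  expect_equal(st$intra_max[st$species == "A"], 0)
  expect_equal(st$inter_min, c(0.21, 0.21))
  expect_true(all(st$inter_capped))
  expect_true(all(is.na(st$nearest_neighbor)))
  expect_error(speciesStats(g, c(A1 = "A")), "unlabeled")
})

test_that("species stats are invariant to input order under canonical grouping", {
  set.seed(73)
  sim <- simulateSpeciesDataset(3, 3, 220, 0.01, 0.10, seed = 3)
  labels <- setNames(sim$labels$species, sim$labels$sequence_id)
  seqs <- as.character(sim$records)
  st1 <- speciesStats(buildGroups(seqs), labels)
  st2 <- speciesStats(buildGroups(seqs[sample(length(seqs))]), labels)
  expect_equal(st1, st2)
})

test_that("locus comparison ranks loci by intra:inter ratio", {
  coi <- data.frame(species = c("s1", "s2", "s3"), locus = "COI",
                    intra_max = c(0.0021, 0.0000, 0.0000),
                    inter_min = c(0.0216, 0.0930, 0.05),
                    inter_capped = FALSE)
  its <- data.frame(species = c("s1", "s2", "s3"), locus = "ITS",
                    intra_max = c(0.0000, 0.0022, 0.0000),
                    inter_min = c(0.0733, 0.0511, 0.06),
                    inter_capped = FALSE)
  cmp <- compareLoci(coi, its)
  # s1: COI ratio 0.0972, ITS ratio 0 -> ITS better
  expect_equal(cmp$ratio_COI[1], 0.0021 / 0.0216)
  expect_equal(cmp$ratio_ITS[1], 0)
  expect_equal(cmp$better_locus[1], "ITS")
  # s2: COI ratio 0, ITS ratio > 0 -> COI better
  expect_equal(cmp$better_locus[2], "COI")
  # s3: both intra zero -> tie
  expect_equal(cmp$better_locus[3], "TIE")
  # inter/intra ("gap") orientation: infinite when intra is zero
  expect_true(is.infinite(cmp$gap_ITS[1]))
  expect_warning(compareLoci(coi[1:2, ], its), "skipped")
})

test_that("the fixture reproduces the published extremes and row counts", {
  rows <- fixtureToDivergenceRows(loadDivergenceFixture())
  its <- summaryReport(rows$ITS)
  coi <- summaryReport(rows$COI)
  expect_equal(its$intra_max_max, 0.0747)
  expect_equal(coi$intra_max_max, 0.0064)
  expect_equal(its$inter_min_min, 0.0096)  # capped entries are bounds, not data
  expect_equal(coi$inter_min_min, 0.0020)
  expect_equal(its$n_capped, 19)
  expect_equal(coi$n_capped, 0)
  # capped cells enter the moments at the cap value
  expect_equal(max(rows$ITS$inter_min), 0.21)
  # rule-based locus comparison runs over the 33 single-species rows
  cmp <- compareLoci(rows$COI[!is.na(rows$COI$intra_max), ],
                     rows$ITS[!is.na(rows$ITS$intra_max), ])
  expect_equal(nrow(cmp), 33)
  expect_true(all(cmp$better_locus %in% c("COI", "ITS", "TIE")))
})

test_that("degenerate summaries behave: all-zero rows and all-NA intra", {
  zero <- data.frame(species = c("x", "y"), locus = "ITS",
                     intra_max = c(0, 0), inter_min = c(0, 0),
                     inter_capped = FALSE)
  s <- summaryReport(zero)
  expect_equal(s$intra_max_max, 0)
  expect_equal(s$inter_min_min, 0)
  expect_equal(s$intra_mean, 0)
  na_intra <- data.frame(species = "x", locus = "ITS", intra_max = NA_real_,
                         inter_min = 0.1, inter_capped = FALSE)
  s2 <- summaryReport(na_intra)
  expect_true(is.na(s2$intra_max_max))
  expect_equal(s2$inter_min_min, 0.1)
})
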