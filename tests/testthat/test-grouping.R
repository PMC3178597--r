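# Greedy alignment-group construction.

make_mutant <- function(base, positions) {
  ch <- strsplit(base, "")[[1]]
  ch[positions] <- vapply(ch[positions], function(b) {
    sample(setdiff(c("A", "C", "G", "T"), b), 1)
  }, character(1))
  paste(ch, collapse = "")
}

test_that("identity and overlap thresholds govern joining", {
  set.seed(51)
  s <- random_dna(200)
  g <- buildGroups(c(a = s, b = s), groupingParams())
  expect_equal(nGroups(g), 1L)
  # ~60% identity: two singletons
  far <- make_mutant(s, sample(200, 80))
  g2 <- buildGroups(c(a = s, b = far), groupingParams())
  expect_equal(nGroups(g2), 2L)
  expect_null(groupMSA(g2, groupIds(g2)[1]))
  # A,B at 85%; C at ~72% to both: C stays out. Substitutions are scattered:
  # a contiguous divergent block would let the aligner gap around it.
  A <- s
  posB <- sample(200, 30)
  B <- make_mutant(s, posB)
  C <- make_mutant(s, sample(setdiff(1:200, posB), 56))
  expect_gte(alignPair(A, B)$identity, 0.85)
  expect_lt(alignPair(A, C)$identity, 0.80)
  expect_lt(alignPair(B, C)$identity, 0.80)
  g3 <- buildGroups(c(A = A, B = B, C = C), groupingParams())
  parts <- split(groupMembership(g3)$sequence_id, groupMembership(g3)$group_id)
  expect_setequal(unname(vapply(parts, paste, character(1), collapse = "+")),
                  c("A+B", "C"))
  # short overlap blocks joining even at high identity
  g4 <- buildGroups(c(a = substr(s, 1, 80), b = substr(s, 1, 80)),
                    groupingParams(min_overlap = 100))
  expect_equal(nGroups(g4), 2L)
})

test_that("output is a partition and multi-member groups carry an MSA", {
  set.seed(52)
  sim <- simulateSpeciesDataset(4, 3, 250, 0.01, 0.12, seed = 7)
  g <- buildGroups(sim$records)
  mem <- groupMembership(g)
  expect_setequal(mem$sequence_id, names(sim$records))
  expect_equal(anyDuplicated(mem$sequence_id), 0L)
  for (gid in groupIds(g)) {
    ids <- groupMembers(g, gid)
    if (length(ids) >= 2) {
      msa <- groupMSA(g, gid)
      expect_setequal(names(msa), ids)
      expect_equal(length(unique(Biostrings::width(msa))), 1L)
    }
  }
  expect_error(buildGroups(character(0)), "no input")
})

test_that("canonical order makes grouping a pure function of the input set", {
  set.seed(53)
  sim <- simulateSpeciesDataset(3, 3, 220, 0.02, 0.15, seed = 9)
  seqs <- as.character(sim$records)
  g1 <- buildGroups(seqs)
  g2 <- buildGroups(seqs[sample(length(seqs))])
  expect_equal(groupMembership(g1), groupMembership(g2))
})

test_that("raising the identity threshold refines the partition on clean data", {
  set.seed(54)
  sim <- simulateSpeciesDataset(4, 3, 220, 0.02, 0.30, seed = 13)
  part_at <- function(tau) {
    g <- buildGroups(sim$records, groupingParams(min_identity = tau))
    m <- groupMembership(g)
    split(m$sequence_id, m$group_id)
  }
  lo <- part_at(0.70)
  hi <- part_at(0.90)
  group_of <- function(parts) {
    out <- character(0)
    for (nm in names(parts)) out[parts[[nm]]] <- nm
    out
  }
  glo <- group_of(lo); ghi <- group_of(hi)
  # every high-threshold group sits inside one low-threshold group
  for (p in hi) expect_equal(length(unique(glo[p])), 1L)
  # permissive settings collapse everything that is mutually alignable
  g_all <- buildGroups(sim$records,
                       groupingParams(min_identity = 0.01, min_overlap = 1))
  expect_equal(nGroups(g_all), 1L)
})

test_that("order sensitivity: stable cases agree, ambiguous chains may not", {
  set.seed(55)
  s <- random_dna(200)
  # mutually >95% identical: one group under every order
  near <- c(a = s, b = make_mutant(s, 1:5), c = make_mutant(s, 6:10))
  res <- groupingOrderSensitivity(near, n_shuffles = 6, seed = 2)
  expect_equal(res$agreement, 1.0)
  # mutually <60% identical: all singletons under every order
  far <- c(a = s, b = make_mutant(s, sample(200, 90)),
           c = make_mutant(s, sample(200, 90)))
  res2 <- groupingOrderSensitivity(far, n_shuffles = 6, seed = 3)
  expect_equal(res2$agreement, 1.0)
  # chain A~B ~85%, B~C ~85%, A~C ~70% (scattered): the 6 orders disagree
  posA <- sample(200, 30)
  A <- make_mutant(s, posA); B <- s
  C <- make_mutant(s, sample(setdiff(1:200, posA), 30))
  chain <- c(A = A, B = B, C = C)
  perms <- list(c(1,2,3), c(1,3,2), c(2,1,3), c(2,3,1), c(3,1,2), c(3,2,1))
  parts <- lapply(perms, function(p) {
    g <- buildGroups(chain[p], groupingParams(order_policy = "input"))
    m <- groupMembership(g)
    sort(vapply(split(m$sequence_id, m$group_id), paste, character(1),
                collapse = "+"))
  })
  expect_gt(length(unique(parts)), 1L)
})
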