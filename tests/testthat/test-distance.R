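# K2P distances, distance matrices, neighbor joining, monophyly.

test_that("K2P counts transitions/transversions and applies the closed form", {
  r0 <- k2pDistance(strrep("ACGT", 25), strrep("ACGT", 25))
  expect_equal(r0$P, 0)
  expect_equal(r0$Q, 0)
  expect_equal(r0$d, 0)
  # 20 sites, 2 transitions, 1 transversion
  a <- strrep("A", 20)
  b <- paste0("G", "G", "C", strrep("A", 17))
  r <- k2pDistance(a, b)
  expect_equal(r$P, 0.10)
  expect_equal(r$Q, 0.05)
  expect_equal(r$d, -0.5 * log(0.75 * sqrt(0.90)))
  # pairwise deletion drops the column with a gap or ambiguity in either row
  r2 <- k2pDistance("AC-GT", "ACNGT")
  expect_equal(r2$sites, 4L)
  expect_equal(r2$d, 0)
  expect_error(k2pDistance("ACGT", "ACG"), "equal length")
})

test_that("K2P is undefined (never fabricated) at saturation", {
  r <- k2pDistance(strrep("A", 10), strrep("G", 10))  # P = 1
  expect_true(is.na(r$d))
  expect_equal(r$P, 1)
  r2 <- k2pDistance(strrep("A", 10), strrep("C", 10))  # Q = 1
  expect_true(is.na(r2$d))
  r3 <- k2pDistance("----", "ACGT")
  expect_equal(r3$sites, 0L)
  expect_true(is.na(r3$d))
})

test_that("K2P agrees with an independent per-site oracle and dominates p-distance", {
  set.seed(61)
  for (i in 1:60) {
    L <- sample(50:300, 1)
    a <- random_dna(L)
    ch <- strsplit(a, "")[[1]]
    k <- rbinom(1, L, 0.15)
    if (k > 0) {
      pos <- sample(L, k)
      ch[pos] <- vapply(ch[pos], function(x) {
        sample(setdiff(c("A", "C", "G", "T"), x), 1)
      }, character(1))
    }
    b <- paste(ch, collapse = "")
    mine <- k2pDistance(a, b)
    ora <- brute_k2p(a, b)
    expect_equal(mine$sites, ora$sites)
    expect_equal(mine$d, ora$d, tolerance = 1e-12)
    if (!is.na(mine$d)) expect_gte(mine$d, ora$p)
    expect_equal(mine$d, k2pDistance(b, a)$d)
  }
})

test_that("K2P matches ape's K80 distances on random alignments", {
  set.seed(62)
  for (i in 1:10) {
    sim <- simulateSpeciesDataset(2, 3, 400, 0.02, 0.15, seed = i)
    msa <- progressiveMSA(sim$records)
    mine <- distances(k2pMatrix(msa))
    bin <- ape::as.DNAbin(strsplit(as.character(msa), ""))
    ref <- as.matrix(ape::dist.dna(bin, model = "K80",
                                   pairwise.deletion = TRUE))
    expect_equal(mine, ref[rownames(mine), colnames(mine)],
                 tolerance = 1e-10)
  }
})

test_that("distance matrices are symmetric, zero-diagonal, NA-flagged", {
  set.seed(63)
  msa <- c(a = "ACGTACGTAC", b = "ACGTACGTAC", c = "ACGTACGTAC")
  m0 <- k2pMatrix(msa)
  expect_true(all(distances(m0) == 0))
  sat <- c(a = strrep("A", 30), b = strrep("G", 30), c = random_dna(30))
  ms <- k2pMatrix(sat)
  und <- undefinedPairs(ms)
  expect_true(nrow(und) >= 1)
  expect_true(any(und$id_a == "a" & und$id_b == "b"))
  for (i in 1:10) {
    sim <- simulateSpeciesDataset(2, 2, 100, 0.05, 0.2, seed = 100 + i)
    m <- distances(k2pMatrix(progressiveMSA(sim$records)))
    expect_equal(m, t(m))
    expect_true(all(diag(m) == 0))
    expect_true(all(m >= 0, na.rm = TRUE))
  }
  expect_error(k2pMatrix(c(a = "ACGT", b = "ACG")), "ragged")
})

test_that("complete deletion drops columns with any gap or ambiguity", {
  msa <- c(a = "ACGTAC", b = "AC-TAC", c = "ACGTNC")
  m <- k2pMatrix(msa, deletion = "complete")
  # only columns 1,2,4,6 survive for every pair
  expect_true(all(distances(m) == 0))
})

test_that("neighbor joining recovers additive trees exactly", {
  two <- matrix(c(0, 0.3, 0.3, 0), 2, dimnames = list(c("A", "B"), c("A", "B")))
  tr2 <- njTree(two)
  expect_equal(sort(tr2$edge.length), c(0.15, 0.15))
  # 3-taxon closed form
  m3 <- matrix(c(0, .2, .3, .2, 0, .4, .3, .4, 0), 3,
               dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr3 <- njTree(m3)
  pend <- setNames(tr3$edge.length[tr3$edge[, 2] <= 3],
                   tr3$tip.label[tr3$edge[tr3$edge[, 2] <= 3, 2]])
  expect_equal(pend[c("a", "b", "c")], c(a = 0.05, b = 0.15, c = 0.25))
  set.seed(64)
  for (i in 1:20) {
    case <- random_additive_case(sample(4:10, 1))
    rec <- njTree(case$dist)
    expect_equal(phangorn::RF.dist(ape::unroot(case$tree), ape::unroot(rec)), 0)
    cd <- ape::cophenetic.phylo(rec)
    cd <- cd[rownames(case$dist), colnames(case$dist)]
    expect_lt(max(abs(cd - case$dist)), 1e-9)
  }
})

test_that("neighbor joining matches ape's nj topologically on noisy matrices", {
  set.seed(65)
  for (i in 1:8) {
    case <- random_additive_case(7)
    noisy <- case$dist + matrix(runif(49, 0, 0.005), 7, 7)
    noisy <- (noisy + t(noisy)) / 2
    diag(noisy) <- 0
    mine <- njTree(noisy)
    ref <- ape::nj(as.dist(noisy))
    expect_equal(phangorn::RF.dist(ape::unroot(mine), ape::unroot(ref)), 0)
  }
})

test_that("undefined entries block tree building with a helpful error", {
  m <- matrix(c(0, NA, NA, 0), 2, dimnames = list(c("A", "B"), c("A", "B")))
  expect_error(njTree(m), "applyCap")
})

test_that("species monophyly matches brute-force bipartition enumeration", {
  t1 <- ape::read.tree(text = "((A1:1,A2:1):1,(B1:1,B2:1):1);")
  expect_equal(speciesMonophyly(t1, c(A1 = "A", A2 = "A", B1 = "B", B2 = "B")),
               c(A = TRUE, B = TRUE))
  t2 <- ape::read.tree(text = "((A1:1,B1:1):1,(A2:1,B2:1):1);")
  expect_equal(speciesMonophyly(t2, c(A1 = "A", A2 = "A", B1 = "B", B2 = "B")),
               c(A = FALSE, B = FALSE))
  expect_error(speciesMonophyly(t1, c(A1 = "A")), "unlabeled")
  set.seed(66)
  for (i in 1:15) {
    tr <- ape::rtree(8)
    labels <- setNames(sample(c("x", "y", "z"), 8, replace = TRUE),
                       tr$tip.label)
    mine <- speciesMonophyly(tr, labels)
    ora <- brute_monophyly(tr, labels)
    expect_equal(mine[sort(names(mine))], ora[sort(names(ora))])
  }
})
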