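test_that("universal-tail correction subtracts the printed tail lengths", {
  expect_equal(adjustAlleleSizes(220, "T7"), 200)
  expect_equal(adjustAlleleSizes(150, "M13"), 132)
  expect_equal(adjustAlleleSizes(150, "M13R"), 132)
  expect_equal(adjustAlleleSizes(150, "D12S1090f"), 132)
  expect_equal(adjustAlleleSizes(c(100, 110), "T7"), c(80, 90))
  expect_error(adjustAlleleSizes(100, "X"), "unknown universal tail")
})

test_that("Bruvo distance reproduces hand-derived cases", {
  loci <- data.frame(locus = "L1", repeat_bp = 1)
  # identical genotypes
  g <- list(L1 = c(20, 23))
  expect_equal(bruvoDistance(g, g, loci), 0)
  # {20,23} vs {20,24}: best matching (0 + (1 - 2^-1)) / 2 = 0.25
  expect_equal(bruvoDistance(list(L1 = c(20, 23)), list(L1 = c(20, 24)), loci),
               0.25)
  # far alleles saturate towards 1
  d <- bruvoDistance(list(L1 = c(10, 10)), list(L1 = c(35, 40)), loci)
  expect_gte(d, 1 - 2^-20)
  expect_lte(d, 1)
})

test_that("distances average over shared loci and flag disjoint genotypes", {
  loci <- data.frame(locus = c("L1", "L2"), repeat_bp = c(2, 2))
  g1 <- list(L1 = c(100, 104), L2 = c(100, 100))
  g2 <- list(L1 = c(100, 104), L2 = c(102, 102))
  expect_equal(bruvoDistance(g1, g2, loci), mean(c(0, 1 - 2^-1)))
  g3 <- list(L1 = c(100, 104))
  g4 <- list(L2 = c(100, 100))
  expect_warning(d <- bruvoDistance(g3, g4, loci), "no shared")
  expect_true(is.na(d))
})

test_that("Bruvo equals the brute-force oracle on random mixed-ploidy pairs", {
  set.seed(21)
  loci <- data.frame(locus = c("L1", "L2", "L3"), repeat_bp = c(2, 3, 2))
  for (i in 1:60) {
    p1 <- sample(c(2, 3, 4), 1)
    p2 <- sample(c(2, 3, 4), 1)
    g1 <- randomGenotype(loci, ploidy = 4, nAlleles = p1)
    g2 <- randomGenotype(loci, ploidy = 4, nAlleles = p2)
    expect_equal(bruvoDistance(g1, g2, loci), bruvoOracle(g1, g2, loci),
                 tolerance = 1e-12)
  }
})

test_that("the distance matrix is symmetric, bounded and zero-diagonal", {
  gen <- divergentGenotypes(seed = 22, nCultivars = 12,
                            hexaploidPops = 1L)
  D <- bruvoDist(gen$genotypes)
  expect_equal(D, t(D))
  expect_equal(unname(diag(D)), rep(0, 12))
  expect_true(all(D >= 0 & D <= 1))
})

test_that("NJ reconstructs a 4-taxon additive matrix exactly", {
  # distances on the tree ((A:1,B:2):1,(C:3,D:1))
  D <- matrix(0, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  D["A", "B"] <- 3; D["A", "C"] <- 5; D["A", "D"] <- 3
  D["B", "C"] <- 6; D["B", "D"] <- 4; D["C", "D"] <- 4
  D <- D + t(D)
  tr <- njTree(D)
  # topology: AB | CD split
  ref <- ape::unroot(ape::read.tree(text = "((A:1,B:2):1,(C:3,D:1));"))
  expect_equal(unclass(ape::dist.topo(tr, ref))[1], 0, ignore_attr = TRUE)
  # branch lengths recovered exactly
  tipLen <- stats::setNames(tr$edge.length[match(seq_len(4), tr$edge[, 2])],
                            tr$tip.label)
  expect_equal(tipLen[LETTERS[1:4]], c(A = 1, B = 2, C = 3, D = 1))
  internal <- tr$edge.length[tr$edge[, 2] > 4]
  expect_equal(sum(internal), 1)
})

test_that("NJ handles 2 taxa and rejects incomplete matrices", {
  D2 <- matrix(c(0, 0.4, 0.4, 0), 2, 2, dimnames = list(c("A", "B"),
                                                        c("A", "B")))
  tr <- njTree(D2)
  expect_equal(sum(tr$edge.length), 0.4)
  Dna <- D2; Dna[1, 2] <- NA
  expect_error(njTree(Dna), "complete")
})

test_that("NJ recovers random additive trees (Robinson-Foulds = 0)", {
  set.seed(23)
  for (i in 1:15) {
    tr0 <- ape::rtree(8, br = stats::runif)
    D <- ape::cophenetic.phylo(tr0)
    tr <- njTree(D)
    expect_equal(unclass(ape::dist.topo(ape::unroot(tr0), tr))[1], 0,
                 ignore_attr = TRUE)
  }
})

test_that("clamped NJ trees never carry negative branch lengths", {
  set.seed(24)
  for (i in 1:10) {
    n <- 6
    M <- matrix(stats::runif(n * n, 0.1, 1), n, n)
    D <- (M + t(M)) / 2; diag(D) <- 0
    dimnames(D) <- list(letters[1:n], letters[1:n])
    tr <- njTree(D)
    expect_true(all(tr$edge.length >= 0))
  }
})

test_that("bootstrap supports are deterministic and concordant when clean", {
  gen <- divergentGenotypes(seed = 25, nCultivars = 14, nPopulations = 2)
  t1 <- bootstrapNJ(gen$genotypes, nBoot = 50, seed = 7)
  t2 <- bootstrapNJ(gen$genotypes, nBoot = 50, seed = 7)
  expect_identical(t1$node.label, t2$node.label)
  # the deepest split separates the two populations with full support:
  # check that some internal edge reaches ~100%
  expect_gte(max(t1$node.label, na.rm = TRUE), 95)
  # no bootstrap -> plain tree
  t0 <- bootstrapNJ(gen$genotypes, nBoot = 0)
  expect_null(t0$node.label)
  one <- gen$genotypes
  one@loci <- one@loci[1, , drop = FALSE]
  one@calls <- lapply(one@calls, function(g) g["SSR_A"])
  expect_error(bootstrapNJ(one, nBoot = 10), "at least 2 loci")
})

test_that("DAPC posteriors are proper and kMax is capped", {
  gen <- divergentGenotypes(seed = 26, nCultivars = 15)
  dp <- dapc(gen$genotypes, kMax = 6, nStarts = 20, seed = 2)
  expect_equal(unname(rowSums(dp@posterior)), rep(1, 15), tolerance = 1e-9)
  expect_equal(which.min(dp@bic), dp@k)
  expect_warning(dapc(gen$genotypes, kMax = 40, nStarts = 5, seed = 2),
                 "capped")
})

test_that("DAPC recovers strongly diverged planted populations", {
  gen <- divergentGenotypes(seed = 27, nCultivars = 36, nPopulations = 3)
  dp <- dapc(gen$genotypes, kMax = 8, nStarts = 50, seed = 4)
  expect_equal(dp@k, 3L)
  expect_equal(mclust::adjustedRandIndex(dp@assignments, gen$population), 1)
  # posterior memberships agree with the hard assignment
  expect_equal(unname(apply(dp@posterior, 1, which.max)),
               unname(dp@assignments))
})

test_that("PC-count selection maximises held-out accuracy, ties to fewest", {
  gen <- divergentGenotypes(seed = 28, nCultivars = 30, nPopulations = 3)
  sel <- selectNPCs(gen$genotypes, gen$population,
                    candidates = c(2, 5, 10), folds = 5, seed = 9)
  # perfectly separated data: accuracy 1 everywhere, smallest count wins
  expect_equal(unname(sel$accuracy), rep(1, 3), tolerance = 1e-12)
  expect_equal(sel$nPC, 2)
  sel2 <- selectNPCs(gen$genotypes, gen$population,
                     candidates = c(2, 5, 10), folds = 5, seed = 9)
  expect_identical(sel, sel2)
  expect_error(selectNPCs(gen$genotypes, gen$population, folds = 99),
               "folds")
})
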