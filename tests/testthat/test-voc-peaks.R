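# build a peak table directly from a concentration matrix
makePeakTable <- function(conc, mz, nBlank, timepoints = NULL) {
  nFruit <- ncol(conc) - nBlank
  tp <- if (is.null(timepoints)) rep("harvest", nFruit) else timepoints
  meta <- data.frame(
    cultivar = c(sprintf("C%02d", seq_len(nFruit)), rep(NA, nBlank)),
    timepoint = c(tp, rep(NA, nBlank)),
    replicate = 1L,
    is_blank = rep(c(FALSE, TRUE), c(nFruit, nBlank)))
  PeakTable(conc = conc, mz = mz, sampleData = meta)
}

test_that("a strongly separated peak is retained, an all-zero peak removed", {
  set.seed(1)
  strong <- c(stats::rlnorm(12, log(100), 0.1), stats::rlnorm(6, log(1), 0.1))
  zero <- rep(0, 18)
  pt <- makePeakTable(rbind(strong, zero), c(50.0, 60.0), nBlank = 6)
  nf <- noiseFilter(pt)
  expect_true(nf$retained[nf$mz == 50.0])
  expect_false(nf$retained[nf$mz == 60.0])
})

test_that("noise filtering demands blanks and reports the Welch test", {
  conc <- matrix(stats::rlnorm(20), 2, 10)
  noBlank <- makePeakTable(conc, c(1, 2), nBlank = 1)
  expect_error(noiseFilter(noBlank), "blank")
  pt <- makePeakTable(conc, c(1, 2), nBlank = 4)
  nf <- noiseFilter(pt)
  expect_true(all(nf$test == "welch-one-sided-log"))
  expect_true(all(is.finite(nf$p)))
})

test_that("null peaks are retained at about the type-I rate alpha", {
  set.seed(33)
  nPeaks <- 1000
  conc <- matrix(stats::rlnorm(nPeaks * 18, log(0.05), 0.4), nPeaks, 18)
  pt <- makePeakTable(conc, seq_len(nPeaks) + 0.5, nBlank = 6)
  nf <- noiseFilter(pt, alpha = 0.05)
  rate <- mean(nf$retained)
  se <- sqrt(0.05 * 0.95 / nPeaks)
  expect_lt(abs(rate - 0.05), 2 * se + 1e-9)
})

test_that("an exact-multiple isotope is removed and its parent retained", {
  set.seed(2)
  parent <- stats::rlnorm(30, log(50), 0.6)
  iso <- parent * 0.011
  other <- stats::rlnorm(30, log(20), 0.6)
  pt <- makePeakTable(rbind(parent, iso, other),
                      c(81.070, 82.073, 99.080), nBlank = 0)
  cf <- correlationFilter(pt)
  expect_true(cf$retained[cf$mz == 81.070])
  expect_false(cf$retained[cf$mz == 82.073])
  expect_equal(cf$partner_mz[cf$mz == 82.073], 81.070)
  expect_true(cf$retained[cf$mz == 99.080])
})

test_that("correlated chains contract to a single representative", {
  set.seed(3)
  base <- stats::rlnorm(40, log(10), 0.5)
  # A ~ B ~ C pairwise exactly proportional: one component, lowest m/z kept
  pt <- makePeakTable(rbind(base, base * 0.2, base * 0.04),
                      c(120.1, 121.1, 122.1), nBlank = 0)
  cf <- correlationFilter(pt)
  expect_equal(sum(cf$retained), 1L)
  expect_true(cf$retained[cf$mz == 120.1])
  expect_equal(cf$partner_mz[!cf$retained], c(120.1, 120.1))
})

test_that("independent peaks survive; constant peaks are uncorrelated", {
  set.seed(4)
  a <- stats::rlnorm(100, log(5), 0.5)
  b <- stats::rlnorm(100, log(7), 0.5)
  konst <- rep(2, 100)
  pt <- makePeakTable(rbind(a, b, konst), c(10, 20, 30), nBlank = 0)
  expect_message(cf <- correlationFilter(pt), "constant")
  expect_true(all(cf$retained))
})

test_that("reducePeaks partitions the input and drops blanks", {
  co <- suppressWarnings(simulateCohort(smallConfig(seed = 8)))
  red <- reducePeaks(co@peaks)
  rep_ <- red$report
  allMz <- sort(mzValues(co@peaks))
  got <- sort(c(rep_$retained$mz, rep_$removed_noise$mz,
                rep_$removed_correlated$mz))
  expect_equal(got, allMz)
  expect_equal(length(allMz),
               nrow(rep_$retained) + nrow(rep_$removed_noise) +
                 nrow(rep_$removed_correlated))
  expect_false(any(colData(red$table)$is_blank))
  expect_setequal(mzValues(red$table), rep_$retained$mz)
})

test_that("reduction recovers the planted signal peaks on synthetic truth", {
  cfg <- cohortConfig(nCultivars = 10, nFruit = 1, nVocReplicates = 3,
                      nBlanks = 6, nNoisePeaks = 20, nIsotopePeaks = 6,
                      strainStep = 2, seed = 55)
  co <- suppressWarnings(simulateCohort(cfg))
  red <- reducePeaks(co@peaks)
  roles <- co@truth$peakRole
  signal <- roles$mz[roles$role == "signal"]
  retained <- red$report$retained$mz
  # all isotopes out, nearly all signal in, noise near the type-I rate
  expect_true(all(roles$mz[roles$role == "isotope"] %in%
                    c(red$report$removed_correlated$mz,
                      red$report$removed_noise$mz)))
  expect_gte(mean(signal %in% retained), 0.9)
  nNoiseKept <- sum(roles$mz[roles$role == "noise"] %in% retained)
  expect_lte(nNoiseKept, 5)
})

test_that("filters are invariant to sample and peak permutations", {
  set.seed(6)
  conc <- rbind(stats::rlnorm(20, log(30), 0.4),
                stats::rlnorm(20, log(0.05), 0.4),
                stats::rlnorm(20, log(9), 0.4))
  pt <- makePeakTable(conc, c(40, 50, 60), nBlank = 6)
  nf1 <- noiseFilter(pt)
  sPerm <- sample(ncol(pt)); pPerm <- c(3, 1, 2)
  pt2 <- pt[pPerm, sPerm]
  nf2 <- noiseFilter(pt2)
  expect_equal(nf2$retained[match(nf1$mz, nf2$mz)], nf1$retained)
  cf1 <- correlationFilter(pt)
  cf2 <- correlationFilter(pt2)
  expect_equal(cf2$retained[match(cf1$mz, cf2$mz)], cf1$retained)
})

test_that("annotation matches the packaged library and flags unknowns", {
  ann <- annotatePeaks(c(33.033, 47.043, 999.999))
  expect_equal(ann$identification[1], "Methanol")
  expect_equal(ann$formula[1], "CH4OH+")
  expect_equal(ann$identification[2], "Ethanol")
  expect_equal(ann$formula[2], "C2H6OH+")
  expect_equal(ann$identification[3], "unknown")
  # tolerance is respected
  far <- annotatePeaks(33.05, tolerance = 0.005)
  expect_equal(far$identification, "unknown")
})
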