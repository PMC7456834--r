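test_that("cohort simulation is deterministic given the seed", {
  cfg <- smallConfig(seed = 11)
  a <- suppressWarnings(simulateCohort(cfg))
  b <- suppressWarnings(simulateCohort(cfg))
  expect_identical(a@truth, b@truth)
  expect_identical(assay(a@peaks, "conc"), assay(b@peaks, "conc"))
  expect_identical(a@genotypes@calls, b@genotypes@calls)
  expect_identical(lapply(curves(a), slot, "force"),
                   lapply(curves(b), slot, "force"))
  c2 <- suppressWarnings(simulateCohort(smallConfig(seed = 12)))
  expect_false(identical(assay(a@peaks, "conc"), assay(c2@peaks, "conc")))
})

test_that("curve counts follow the design: cultivars x timepoints x fruit", {
  co <- suppressWarnings(simulateCohort(
    cohortConfig(nCultivars = 2, nFruit = 1, strainStep = 0.5, seed = 3)))
  expect_length(curves(co), 4L)
  meta <- t(vapply(curves(co), function(cv)
    c(cv@cultivar, cv@timepoint), character(2)))
  expect_setequal(paste(meta[, 1], meta[, 2]),
                  c("CV01 harvest", "CV01 postharvest",
                    "CV02 harvest", "CV02 postharvest"))
})

test_that("invalid configurations are rejected naming the field", {
  expect_error(cohortConfig(nCultivars = 0), "nCultivars")
  expect_error(cohortConfig(nBlanks = 0), "nBlanks")
  expect_error(cohortConfig(vocReplicateCV = 0), "CV")
  expect_error(cohortConfig(concFloor = 0), "concFloor")
  expect_error(cohortConfig(hexaploidPops = 9L), "hexaploidPops")
})

test_that("simulated curves respect the mechanogram shape invariants", {
  co <- suppressWarnings(simulateCohort(smallConfig(seed = 5)))
  for (cv in curves(co)[1:6]) {
    expect_true(all(diff(cv@strain) > 0))
    expect_true(all(cv@force >= 0))
    expect_lte(max(cv@strain), 90)
    iMax <- which.max(cv@force)
    expect_gt(iMax, 1)
    expect_lt(iMax, length(cv@force))
  }
})

test_that("strain spacing is consistent with the acquisition settings", {
  # 500 points/s at 100 mm/min over a 12 mm fruit:
  # (100/60 mm/s) / 12 mm * 100% / 500 pt/s per point
  cfg <- cohortConfig(nCultivars = 1, nFruit = 1, seed = 2)
  co <- suppressWarnings(simulateCohort(cfg))
  expected <- (100 / 60) / 12 * 100 / 500
  steps <- diff(curves(co)[[1]]@strain)
  # uniform grid except where the planted nodes are inserted
  expect_equal(sort(unique(round(steps, 10)))[length(unique(round(steps, 10)))],
               round(expected, 10), tolerance = 1e-8)
  expect_equal(stats::median(steps), expected, tolerance = 1e-8)
})

test_that("noise-free generation round-trips through the extractor exactly", {
  params <- list(gradient = 1.5, max_force = 3.6, max_force_strain = 4.0,
                 min_force = 0.8, min_force_strain = 5.8, final_force = 1.4)
  sim <- simulateMechanogram(params, strainStep = 0.25, noiseSd = 0)
  prof <- extractTextureProfile(sim$curve)
  expect_equal(prof[names(sim$truth)], sim$truth, tolerance = 1e-12)
  # area matches the closed-form polyline integral computed independently
  s1 <- 0.4 * params$max_force / params$gradient
  nodesS <- c(0, s1, params$max_force_strain, params$min_force_strain, 90)
  nodesF <- c(0, 0.4 * params$max_force, params$max_force,
              params$min_force, params$final_force)
  expect_equal(unname(sim$truth["area"]), polylineArea(nodesS, nodesF),
               tolerance = 1e-12)
})

test_that("out-of-range parameters are clipped with a warning", {
  expect_warning(
    simulateMechanogram(list(gradient = 0.01, max_force = 3, max_force_strain = 4,
                             min_force = 2.9, min_force_strain = 5,
                             final_force = 2.95), strainStep = 0.5),
    "clipped")
})

test_that("the planted storage shift lowers gradient and raises peak strain", {
  cfg <- cohortConfig(nCultivars = 8, nFruit = 2, textureShiftSd = 0,
                      fruitCV = 0, forceNoiseSd = 0, strainStep = 0.5,
                      seed = 21)
  co <- suppressWarnings(simulateCohort(cfg))
  tp <- co@truth$curveParams
  h <- tp[tp$timepoint == "harvest", ]
  p <- tp[tp$timepoint == "postharvest", ]
  h <- h[order(h$cultivar, h$fruit), ]; p <- p[order(p$cultivar, p$fruit), ]
  expect_true(all(p$gradient < h$gradient))
  expect_true(all(p$max_force_strain > h$max_force_strain))
})

test_that("planted isotopes are exact scalar multiples of their parents", {
  co <- suppressWarnings(simulateCohort(smallConfig(seed = 9)))
  roles <- co@truth$peakRole
  conc <- assay(co@peaks, "conc")
  mz <- mzValues(co@peaks)
  iso <- which(roles$role == "isotope")
  expect_gt(length(iso), 0)
  fruit <- !colData(co@peaks)$is_blank
  for (i in iso) {
    parent <- which(mz == roles$parent_mz[i])
    r <- cor(conc[i, fruit], conc[parent, fruit])
    expect_equal(r, 1.0, tolerance = 1e-12)
    expect_equal(conc[i, fruit] / conc[parent, fruit],
                 rep(roles$isotope_factor[i], sum(fruit)),
                 tolerance = 1e-12, ignore_attr = TRUE)
  }
})

test_that("blank-equivalent noise peaks are exchangeable with blanks", {
  cfg <- cohortConfig(nCultivars = 10, nFruit = 1, nVocReplicates = 3,
                      nBlanks = 30, nNoisePeaks = 40, strainStep = 1,
                      seed = 31)
  co <- suppressWarnings(simulateCohort(cfg))
  roles <- co@truth$peakRole
  conc <- assay(co@peaks, "conc")
  blanks <- colData(co@peaks)$is_blank
  noiseRows <- which(roles$role == "noise")
  # KS test of noise-peak values (all samples) against blank-channel values
  # of other noise peaks: p-values should look uniform, not concentrated at 0
  ps <- vapply(noiseRows[1:20], function(i) {
    ref <- as.vector(conc[setdiff(noiseRows, i), blanks])
    suppressWarnings(stats::ks.test(conc[i, ], ref)$p.value)
  }, numeric(1))
  expect_gt(mean(ps > 0.05), 0.8)
  expect_gt(min(ps), 1e-4)
})

test_that("planted SI signs propagate to the simulated concentrations", {
  cfg <- cohortConfig(nCultivars = 46, nFruit = 1, vocShiftSd = 0,
                      strainStep = 2, seed = 41)
  co <- suppressWarnings(simulateCohort(cfg))
  vc <- cfg@vocClasses
  h <- cultivarMeanMatrix(co@peaks, "harvest")
  p <- cultivarMeanMatrix(co@peaks, "postharvest")
  directional <- which(vc$directional & vc$log2_shift != 0)
  si <- log2(colMeans(p)[seq_len(nrow(vc))] / colMeans(h)[seq_len(nrow(vc))])
  agree <- sign(si[directional]) == sign(vc$log2_shift[directional])
  expect_gte(mean(agree), 0.95)
})
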