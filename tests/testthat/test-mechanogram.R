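test_that("the worked piecewise-linear example extracts exactly", {
  # nodes (0,0) -> (50,5) -> (70,1) -> (90,2); trapezoid areas 125 + 60 + 30
  cv <- makeCurve(c(0, 50, 70, 90), c(0, 5, 1, 2), step = 0.5)
  p <- extractTextureProfile(cv)
  expect_equal(unname(p["max_force"]), 5)
  expect_equal(unname(p["max_force_strain"]), 50)
  expect_equal(unname(p["min_force"]), 1)
  expect_equal(unname(p["min_force_strain"]), 70)
  expect_equal(unname(p["final_force"]), 2)
  expect_equal(unname(p["area"]), 215)
  # initial region is a straight line of slope 5/50 = 0.1 N/%
  expect_equal(unname(p["gradient"]), 0.1, tolerance = 1e-12)
})

test_that("gradient unit modes: raw N/% and stress-based MPa", {
  cv <- makeCurve(c(0, 50, 70, 90), c(0, 5, 1, 2), step = 0.5)
  raw <- extractTextureProfile(cv, gradientMode = "raw")["gradient"]
  mpa <- extractTextureProfile(cv, gradientMode = "mpa")["gradient"]
  # stress mode: divide force by the 4 mm probe area (12.566 mm^2),
  # strain as a fraction -> factor 100 / (pi * 4)
  expect_equal(unname(mpa), unname(raw) * 100 / (pi * 4), tolerance = 1e-12)
})

test_that("degenerate and invalid curves raise informative errors", {
  flat <- new("MechCurve", strain = seq(0, 90, by = 5),
              force = rep(0, 19), cultivar = "Z", timepoint = "harvest",
              fruit = "7", acquisitionRate = 500)
  expect_error(extractTextureProfile(flat), "degenerate")
  rising <- new("MechCurve", strain = seq(0, 90, by = 5),
                force = seq(0, 4.5, by = 0.25), cultivar = "Z",
                timepoint = "harvest", fruit = "8", acquisitionRate = 500)
  expect_error(extractTextureProfile(rising), "degenerate.*8")
  expect_error(
    new("MechCurve", strain = c(0, 1, 1, 2:12), force = rep(1, 14),
        cultivar = "Z", timepoint = "harvest", fruit = "9",
        acquisitionRate = 500),
    "strictly increasing")
})

test_that("extraction is scale-equivariant in force", {
  cv <- makeCurve(c(0, 40, 60, 90), c(0, 4, 1.2, 1.8), step = 0.5)
  p1 <- extractTextureProfile(cv)
  cv2 <- new("MechCurve", strain = cv@strain, force = cv@force * 3,
             cultivar = "T", timepoint = "harvest", fruit = "1",
             acquisitionRate = 500)
  p2 <- extractTextureProfile(cv2)
  forceLike <- c("gradient", "max_force", "min_force", "area", "final_force")
  expect_equal(p2[forceLike], 3 * p1[forceLike], tolerance = 1e-10)
  strains <- c("max_force_strain", "min_force_strain")
  expect_equal(p2[strains], p1[strains])
})

test_that("a storage shift that widens the ramp lowers the gradient", {
  base <- list(gradient = 1.8, max_force = 3.8, max_force_strain = 3.4,
               min_force = 0.9, min_force_strain = 5.4, final_force = 1.5)
  shifted <- base
  shifted$gradient <- base$gradient * 2^-0.95
  shifted$max_force_strain <- base$max_force_strain * 2^0.31
  g1 <- extractTextureProfile(
    simulateMechanogram(base, strainStep = 0.25)$curve)["gradient"]
  g2 <- extractTextureProfile(
    simulateMechanogram(shifted, strainStep = 0.25)$curve)["gradient"]
  expect_lt(unname(g2), unname(g1))
})

test_that("ties in force are resolved to the first index", {
  # plateau at the maximum and a doubled minimum
  s <- c(0:4, 4.5, 5, 6, 7, 8, 9, 10)
  f <- c(0, 1, 2, 3, 4, 4, 4, 1, 1, 2, 2, 2)
  cv <- new("MechCurve", strain = s, force = f, cultivar = "T",
            timepoint = "harvest", fruit = "1", acquisitionRate = 500)
  p <- extractTextureProfile(cv)
  expect_equal(unname(p["max_force_strain"]), 4)
  expect_equal(unname(p["min_force_strain"]), 6)
})

test_that("summarizeTexture aggregates fruit before cultivars and makes SI", {
  prof <- data.frame(
    cultivar = rep(c("A", "B"), each = 4),
    timepoint = rep(c("harvest", "harvest", "postharvest", "postharvest"), 2),
    fruit = as.character(rep(1:2, 4)),
    max_force = c(1, 3, 4, 4, 3, 3, 3, 3),
    gradient = c(2, 2, 1, 1, 4, 4, 2, 2))
  s <- summarizeTexture(prof)
  # cultivar means first: A harvest max_force (1+3)/2 = 2, postharvest 4
  expect_equal(unname(s$si["A", "max_force"]), 1)    # log2(4/2)
  expect_equal(unname(s$si["B", "max_force"]), 0)
  expect_equal(unname(s$si[, "gradient"]), c(-1, -1), ignore_attr = TRUE)
  row <- s$summary[s$summary$trait == "max_force", ]
  expect_equal(c(row$harvest_min, row$harvest_max, row$harvest_mean),
               c(2, 3, 2.5))
})

test_that("identical profiles at both timepoints give SI exactly zero", {
  prof <- data.frame(cultivar = "A",
                     timepoint = rep(c("harvest", "postharvest"), each = 2),
                     fruit = as.character(rep(1:2, 2)),
                     max_force = rep(3.3, 4), area = rep(150, 4))
  s <- summarizeTexture(prof)
  expect_equal(unname(s$si["A", ]), c(0, 0), ignore_attr = TRUE)
})

test_that("a cultivar present at one timepoint yields missing SI, reported", {
  prof <- data.frame(
    cultivar = c("A", "A", "B"),
    timepoint = c("harvest", "postharvest", "harvest"),
    fruit = c("1", "1", "1"),
    max_force = c(2, 4, 5))
  expect_message(s <- summarizeTexture(prof), "single timepoint")
  expect_true(is.na(s$si["B", "max_force"]))
  expect_equal(unname(s$si["A", "max_force"]), 1)
})

test_that("noisy extraction recovers planted maxima within a few percent", {
  set.seed(71)
  params <- list(gradient = 1.5, max_force = 3.6, max_force_strain = 4.0,
                 min_force = 0.8, min_force_strain = 5.8, final_force = 1.4)
  errs <- replicate(200, {
    sim <- simulateMechanogram(params, strainStep = 0.05, noiseSd = 0.01)
    p <- extractTextureProfile(sim$curve)
    abs(p["max_force"] - sim$truth["max_force"]) / sim$truth["max_force"]
  })
  expect_lt(median(errs), 0.02)
})
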