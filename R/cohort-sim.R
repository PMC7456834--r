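#' @include AllClasses.R
NULL

## canonical order of the six texture curve parameters the generator plants
.CURVE_PARAMS <- c("gradient", "max_force", "max_force_strain",
                   "min_force", "min_force_strain", "final_force")

## canonical peak column name for an m/z value
.mzName <- function(mz) vapply(mz, function(z) sprintf("mz_%.10g", z),
                               character(1))

#' Default texture archetypes
#'
#' Three mechanical archetypes span the cohort: turgid fruit (high initial
#' slope / turgor), firm fruit (high breaking force at moderate slope) and
#' gummy fruit (low slope, large deformation at the force peak).  Means are
#' calibrated to the cohort ranges of the seven compression parameters
#' (gradient in N/%, forces in N, strains in %); the log2 storage-shift
#' columns carry the cohort-average storage index of each parameter
#' (gradient loss -0.95, deformation gain +0.31 at the force peak, etc.).
#'
#' @return data.frame, one row per archetype: `name`, the six curve
#'   parameters, and `shift_<param>` log2 storage shifts.
#' @export
defaultTextureArchetypes <- function() {
  data.frame(
    name = c("turgid", "firm", "gummy"),
    gradient         = c(2.00, 1.45, 1.00),
    max_force        = c(3.90, 4.20, 2.90),
    max_force_strain = c(3.30, 4.00, 4.70),
    min_force        = c(0.95, 0.90, 0.62),
    min_force_strain = c(5.20, 5.80, 6.40),
    final_force      = c(1.60, 1.50, 1.20),
    shift_gradient         = -0.95,
    shift_max_force        =  0.07,
    shift_max_force_strain =  0.31,
    shift_min_force        =  0.21,
    shift_min_force_strain =  0.24,
    shift_final_force      =  0.14,
    stringsAsFactors = FALSE
  )
}

#' Default volatile trait classes
#'
#' One row per simulated mass peak: its compound class, harvest-cohort mean
#' concentration (ug/kg) and planted log2 storage shift.  Values follow the
#' cohort means and storage indices of the major headspace peaks: fermentation
#' volatiles rise during cold storage (ethanol +6.68, acetaldehyde +3.21,
#' esters +0.75..+3.14 log2 units) while terpenes and C6 aldehydes fall.
#' The `directional` flag marks classes with an unambiguous planted sign
#' (used by the direction-recovery checks); `fermentation` marks classes whose
#' shift is amplified or damped by the cultivar storage-response archetype.
#'
#' @return data.frame with columns `class`, `mz`, `harvest_mean`,
#'   `log2_shift`, `directional`, `fermentation`.
#' @export
defaultVocClasses <- function() {
  df <- rbind(
    data.frame(class = "methanol", mz = 33.033, harvest_mean = 2228.26,
               log2_shift = 0.77),
    data.frame(class = "acetaldehyde", mz = 45.031, harvest_mean = 80.78,
               log2_shift = 3.21),
    data.frame(class = "ethanol", mz = 47.043, harvest_mean = 2.44,
               log2_shift = 6.68),
    data.frame(class = "esters",
               mz = c(75.043, 89.055, 103.076, 115.076, 117.092, 131.107),
               harvest_mean = c(5.60, 0.70, 1.04, 0.29, 0.85, 0.23),
               log2_shift = c(0.75, 2.52, 1.44, 0.85, 2.66, 3.14)),
    data.frame(class = "terpenes",
               mz = c(137.134, 135.115, 133.103),
               harvest_mean = c(8.30, 2.42, 0.70),
               log2_shift = c(-1.15, -0.81, -0.33)),
    data.frame(class = "c6_aldehydes",
               mz = c(81.070, 99.080, 101.096, 97.065),
               harvest_mean = c(109.22, 92.50, 4.99, 1.01),
               log2_shift = c(-1.00, -0.61, -0.29, -0.76)),
    data.frame(class = "sulfur",
               mz = c(34.996, 49.011, 63.033),
               harvest_mean = c(1.17, 0.59, 1.62),
               log2_shift = c(-1.82, -1.59, 0.79)),
    data.frame(class = "benzenoids",
               mz = c(107.087, 91.068),
               harvest_mean = c(7.62, 0.57),
               log2_shift = c(0.00, 0.76))
  )
  df$directional <- df$class %in%
    c("ethanol", "acetaldehyde", "esters", "terpenes", "c6_aldehydes")
  df$fermentation <- df$class %in% c("ethanol", "acetaldehyde", "esters")
  df
}

#' Default storage-response archetypes for volatiles
#'
#' Cultivars differ in how strongly fermentation metabolism reacts to cold
#' storage: a small fermentative group shows amplified ethanol/acetaldehyde/
#' ester accumulation, a stable group a damped response, the rest follow the
#' cohort-average trajectory.
#'
#' @return data.frame with columns `name`, `multiplier`, `prob`.
#' @export
defaultVocArchetypes <- function() {
  data.frame(name = c("fermentative", "baseline", "stable"),
             multiplier = c(1.5, 1.0, 0.6),
             prob = c(0.11, 0.64, 0.25),
             stringsAsFactors = FALSE)
}

#' Default SSR locus table
#'
#' Six microsatellite loci with di-/tri-nucleotide repeat motifs, the
#' universal-tail label attached to the forward primer, and a flanking length
#' so simulated allele sizes fall in a realistic 100-250 bp window.
#'
#' @return data.frame with columns `locus`, `repeat_bp`, `tail`, `flank_bp`.
#' @export
defaultLociTable <- function() {
  data.frame(
    locus = paste0("SSR_", LETTERS[1:6]),
    repeat_bp = c(2L, 2L, 3L, 2L, 3L, 2L),
    tail = c("T7", "M13", "M13R", "D12S1090f", "T7", "M13"),
    flank_bp = c(80L, 95L, 110L, 70L, 88L, 102L),
    stringsAsFactors = FALSE
  )
}

#' Construct a cohort configuration
#'
#' Builds a validated [CohortConfig-class].  The defaults reproduce the study
#' design the package targets: 46 cultivars assessed at harvest and after six
#' weeks of cold storage, 20 fruit per cultivar and timepoint on the texture
#' side, 3 headspace replicates and 6 blanks on the volatile side, and four
#' planted genetic populations (one hexaploid) scored at six SSR loci.
#'
#' @param nCultivars,nFruit,nVocReplicates,nBlanks design counts.
#' @param timepoints two assessment labels.
#' @param textureArchetypes see [defaultTextureArchetypes()].
#' @param archetypeProbs sampling weights of the texture archetypes.
#' @param cultivarCV,fruitCV lognormal spread (sd of log) of curve parameters
#'   between cultivars and between fruit within cultivar.
#' @param forceNoiseSd gaussian force noise, fraction of peak force.
#' @param textureShiftSd per-cultivar sd (log2) around the planted texture
#'   storage shifts.
#' @param strainStep strain grid spacing in percent; `NA` (default) derives it
#'   from `testSpeed`, `fruitDiameter` and `acquisitionRate`.
#' @param testSpeed compression speed, mm/min.
#' @param fruitDiameter nominal berry diameter, mm.
#' @param acquisitionRate points per second.
#' @param vocClasses see [defaultVocClasses()].
#' @param vocArchetypes see [defaultVocArchetypes()].
#' @param vocCultivarSdLog between-cultivar lognormal sd of harvest levels.
#' @param vocReplicateCV replicate-level coefficient of variation.
#' @param vocShiftSd per-cultivar sd (log2) around the planted class shift.
#' @param blankMeanLog,blankSdLog log-scale location/spread of blank channels.
#' @param nIsotopePeaks,nNoisePeaks numbers of planted isotope and
#'   blank-equivalent nuisance peaks.
#' @param isotopeNoiseSd multiplicative lognormal noise on isotope channels.
#' @param concFloor trace-level reporting floor, ug/kg.
#' @param nPopulations planted genetic populations K.
#' @param lociTable see [defaultLociTable()].
#' @param hexaploidPops population indices simulated as hexaploid.
#' @param popProbs population sampling weights.
#' @param popDivergence modal-allele separation between populations, repeat units.
#' @param mutationGeomProb geometric parameter of stepwise allele offsets.
#' @param seed base RNG seed.
#' @return a [CohortConfig-class] object.
#' @examples
#' cfg <- cohortConfig(nCultivars = 4, nFruit = 2)
#' cfg@nCultivars
#' @export
cohortConfig <- function(nCultivars = 46, nFruit = 20, nVocReplicates = 3,
                         nBlanks = 6,
                         timepoints = c("harvest", "postharvest"),
                         textureArchetypes = defaultTextureArchetypes(),
                         archetypeProbs = c(0.3, 0.4, 0.3),
                         cultivarCV = 0.10, fruitCV = 0.05,
                         forceNoiseSd = 0.01, textureShiftSd = 0.30,
                         strainStep = NA_real_, testSpeed = 100,
                         fruitDiameter = 12, acquisitionRate = 500,
                         vocClasses = defaultVocClasses(),
                         vocArchetypes = defaultVocArchetypes(),
                         vocCultivarSdLog = 0.6, vocReplicateCV = 0.15,
                         vocShiftSd = 1.0,
                         blankMeanLog = log(0.05), blankSdLog = 0.4,
                         nIsotopePeaks = 6, isotopeNoiseSd = 0,
                         nNoisePeaks = 20, concFloor = 1e-3,
                         nPopulations = 4, lociTable = defaultLociTable(),
                         hexaploidPops = 1L, popProbs = c(0.07, 0.31, 0.31, 0.31),
                         popDivergence = 6, mutationGeomProb = 0.5,
                         seed = 1L) {
  if (length(archetypeProbs) != nrow(textureArchetypes))
    archetypeProbs <- rep(1, nrow(textureArchetypes))
  if (length(popProbs) != nPopulations)
    popProbs <- rep(1, nPopulations)
  obj <- new("CohortConfig",
    nCultivars = as.integer(nCultivars), nFruit = as.integer(nFruit),
    nVocReplicates = as.integer(nVocReplicates), nBlanks = as.integer(nBlanks),
    timepoints = as.character(timepoints),
    textureArchetypes = textureArchetypes,
    archetypeProbs = as.numeric(archetypeProbs),
    cultivarCV = cultivarCV, fruitCV = fruitCV, forceNoiseSd = forceNoiseSd,
    textureShiftSd = textureShiftSd,
    strainStep = strainStep, testSpeed = testSpeed,
    fruitDiameter = fruitDiameter, acquisitionRate = acquisitionRate,
    vocClasses = vocClasses, vocArchetypes = vocArchetypes,
    vocCultivarSdLog = vocCultivarSdLog, vocReplicateCV = vocReplicateCV,
    vocShiftSd = vocShiftSd, blankMeanLog = blankMeanLog,
    blankSdLog = blankSdLog,
    nIsotopePeaks = as.integer(nIsotopePeaks),
    isotopeNoiseSd = isotopeNoiseSd,
    nNoisePeaks = as.integer(nNoisePeaks), concFloor = concFloor,
    nPopulations = as.integer(nPopulations), lociTable = lociTable,
    hexaploidPops = as.integer(hexaploidPops),
    popProbs = as.numeric(popProbs), popDivergence = popDivergence,
    mutationGeomProb = mutationGeomProb, seed = as.integer(seed))
  ok <- validObject(obj, test = TRUE)
  if (!isTRUE(ok))
    stop("invalid cohort configuration: ", paste(ok, collapse = "; "))
  obj
}

## strain spacing (percent) implied by the acquisition settings:
## (mm/s) / diameter * 100% / (points/s)
.strainStep <- function(config) {
  if (!is.na(config@strainStep)) return(config@strainStep)
  (config@testSpeed / 60) / config@fruitDiameter * 100 / config@acquisitionRate
}

#' Simulate one mechanogram
#'
#' Builds a piecewise-linear compression profile from planted parameters:
#' an initial segment with slope equal to the planted gradient up to 40% of
#' the peak force, a ramp to the force peak, a drop to the post-peak valley
#' (skin rupture) and a terminal rise to the final force at 90% deformation.
#' Segment endpoints are inserted into the uniform strain grid, so with zero
#' force noise the sampled polyline carries the planted parameters exactly
#' (closed-form ground truth, including the trapezoidal area).
#'
#' Out-of-range parameters are clipped to a valid curve with a warning, and
#' the recorded ground truth reflects the clipped values.
#'
#' @param params named list/vector with `gradient` (N/%), `max_force` (N),
#'   `max_force_strain` (%), `min_force` (N), `min_force_strain` (%),
#'   `final_force` (N).
#' @param cultivar,timepoint,fruit metadata labels.
#' @param strainStep strain grid spacing, percent.
#' @param noiseSd gaussian force noise, fraction of peak force.
#' @param acquisitionRate points per second, stored as curve metadata.
#' @return list with `curve` (a [MechCurve-class]) and `truth` (named numeric
#'   of the seven ground-truth parameters, including `area`).
#' @examples
#' sim <- simulateMechanogram(list(gradient = 1.5, max_force = 3.6,
#'   max_force_strain = 4, min_force = 0.8, min_force_strain = 5.8,
#'   final_force = 1.4), strainStep = 0.5)
#' sim$truth[["area"]]
#' @export
simulateMechanogram <- function(params, cultivar = "CV", timepoint = "harvest",
                                fruit = "1", strainStep = 0.2, noiseSd = 0,
                                acquisitionRate = 500) {
  p <- as.list(params)
  g  <- p$gradient; F_ <- p$max_force; sF <- p$max_force_strain
  f  <- p$min_force; sf <- p$min_force_strain; e <- p$final_force
  clipped <- FALSE
  clip <- function(x, lo, hi) {
    y <- min(max(x, lo), hi)
    if (y != x) clipped <<- TRUE
    y
  }
  F_ <- clip(F_, 1e-3, Inf)
  sF <- clip(sF, 0.5, 85)
  e  <- clip(e, 1e-4, 0.97 * F_)
  f  <- clip(f, 1e-4, 0.95 * e)
  sf <- clip(sf, sF + 0.5, 89.5)
  ## knee at 40% of peak force must precede the peak
  gMin <- 0.4 * F_ / (0.95 * sF)
  g <- clip(g, gMin, Inf)
  if (clipped)
    warning("mechanogram parameters clipped to a valid range for fruit ",
            cultivar, "/", timepoint, "/", fruit)
  s1 <- 0.4 * F_ / g
  nodesS <- c(0, s1, sF, sf, 90)
  nodesF <- c(0, 0.4 * F_, F_, f, e)
  grid <- sort(unique(c(seq(0, 90, by = strainStep), nodesS)))
  force <- stats::approx(nodesS, nodesF, xout = grid)$y
  if (noiseSd > 0) {
    force <- force + stats::rnorm(length(force), 0, noiseSd * F_)
    force[force < 0] <- 0
  }
  area <- sum(diff(nodesS) * (nodesF[-1] + nodesF[-5]) / 2)
  curve <- new("MechCurve", strain = grid, force = force,
               cultivar = as.character(cultivar),
               timepoint = as.character(timepoint),
               fruit = as.character(fruit),
               acquisitionRate = acquisitionRate)
  truth <- c(gradient = g, max_force = F_, max_force_strain = sF,
             min_force = f, min_force_strain = sf, area = area,
             final_force = e)
  list(curve = curve, truth = truth)
}

## draw stepwise allele offsets: signed geometric tail around the mode
.stepOffsets <- function(n, geomProb) {
  mag <- stats::rgeom(n, geomProb)
  sgn <- sample(c(-1L, 1L), n, replace = TRUE)
  mag * sgn
}

#' Simulate mixed-ploidy SSR genotypes from planted populations
#'
#' Each population carries per-locus modal alleles placed on an equally spaced
#' repeat-unit grid (`popDivergence` units apart, with +-1 unit jitter);
#' individual alleles are the population mode plus a signed geometric-tail
#' stepwise offset.  Hexaploid individuals receive six allele draws,
#' tetraploids four.  Allele sizes are reported in base pairs
#' (`flank_bp + repeat_bp * repeat_count`).
#'
#' @param cultivars character vector of cultivar names.
#' @param nPopulations planted number of populations K.
#' @param lociTable see [defaultLociTable()].
#' @param hexaploidPops population indices simulated as hexaploid.
#' @param popProbs population sampling weights.
#' @param popDivergence modal separation between populations, repeat units.
#' @param mutationGeomProb geometric parameter of the stepwise offsets.
#' @param population optional pre-assigned population per cultivar (integer);
#'   drawn from `popProbs` when `NULL`.
#' @return list with `genotypes` (a [GenotypeTable-class]) and `population`
#'   (named integer, the planted population of origin).
#' @export
simulateGenotypes <- function(cultivars, nPopulations = 4,
                              lociTable = defaultLociTable(),
                              hexaploidPops = 1L,
                              popProbs = rep(1, nPopulations),
                              popDivergence = 6, mutationGeomProb = 0.5,
                              population = NULL) {
  n <- length(cultivars)
  if (is.null(population)) {
    population <- sample(seq_len(nPopulations), n, replace = TRUE,
                         prob = popProbs)
    ## guarantee every population is represented when possible
    if (n >= nPopulations) {
      missing <- setdiff(seq_len(nPopulations), unique(population))
      if (length(missing))
        population[sample(n, length(missing))] <- missing
    }
  }
  names(population) <- cultivars
  nLoci <- nrow(lociTable)
  baseMode <- sample(20:40, nLoci, replace = TRUE)
  ## population modes: equally spaced offsets plus small jitter
  modes <- matrix(0L, nrow = nPopulations, ncol = nLoci)
  for (l in seq_len(nLoci))
    modes[, l] <- baseMode[l] + (seq_len(nPopulations) - 1L) *
      as.integer(round(popDivergence)) +
      sample(-1:1, nPopulations, replace = TRUE)
  ploidy <- ifelse(population %in% hexaploidPops, 6L, 4L)
  names(ploidy) <- cultivars
  calls <- vector("list", n)
  names(calls) <- cultivars
  for (i in seq_len(n)) {
    g <- vector("list", nLoci)
    names(g) <- lociTable$locus
    for (l in seq_len(nLoci)) {
      cnt <- modes[population[i], l] +
        .stepOffsets(ploidy[i], mutationGeomProb)
      cnt[cnt < 5L] <- 5L
      g[[l]] <- lociTable$flank_bp[l] + lociTable$repeat_bp[l] * cnt
    }
    calls[[i]] <- g
  }
  gt <- new("GenotypeTable", calls = calls, ploidy = ploidy,
            loci = lociTable[, c("locus", "repeat_bp")])
  list(genotypes = gt, population = population)
}

## lognormal draws with expectation `mean` and coefficient of variation `cv`
.rlnormCV <- function(n, mean, cv) {
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
}

#' Simulate a full phenotyping cohort with known ground truth
#'
#' Generates mechanograms, a volatile peak table and SSR genotypes for a
#' germplasm collection assessed at harvest and after cold storage, together
#' with the planted ground truth every downstream stage can be checked
#' against.  All randomness derives from `config@seed`; the same configuration
#' yields identical cohorts.
#'
#' The peak table contains, besides the planted trait peaks: blank samples,
#' `nNoisePeaks` channels whose distribution equals the blanks' in every
#' sample, and `nIsotopePeaks` isotope channels that are exact scalar
#' multiples (factor in (0, 0.2]) of a parent trait peak.
#'
#' @param config a [CohortConfig-class], see [cohortConfig()].
#' @return a [Cohort-class] with slots `truth`, `curves`, `peaks`,
#'   `genotypes`, `config`.
#' @examples
#' co <- simulateCohort(cohortConfig(nCultivars = 3, nFruit = 1,
#'   nVocReplicates = 2, seed = 7))
#' co
#' @export
simulateCohort <- function(config = cohortConfig()) {
  ok <- validObject(config, test = TRUE)
  if (!isTRUE(ok))
    stop("invalid cohort configuration: ", paste(ok, collapse = "; "))
  set.seed(config@seed)
  n <- config@nCultivars
  cvs <- sprintf("CV%02d", seq_len(n))
  tps <- config@timepoints
  arch <- config@textureArchetypes
  step <- .strainStep(config)

  ## ---- texture -----------------------------------------------------------
  archetype <- arch$name[sample(nrow(arch), n, replace = TRUE,
                                prob = config@archetypeProbs)]
  names(archetype) <- cvs
  cultivarPar <- vector("list", n); names(cultivarPar) <- cvs
  cultivarShift <- vector("list", n); names(cultivarShift) <- cvs
  for (i in seq_len(n)) {
    a <- arch[arch$name == archetype[i], , drop = FALSE]
    base <- unlist(a[1, .CURVE_PARAMS])
    cultivarPar[[i]] <- base *
      exp(stats::rnorm(length(base), 0, config@cultivarCV))
    sh <- unlist(a[1, paste0("shift_", .CURVE_PARAMS)])
    names(sh) <- .CURVE_PARAMS
    cultivarShift[[i]] <- sh +
      stats::rnorm(length(sh), 0, config@textureShiftSd)
  }
  curveList <- vector("list", n * 2L * config@nFruit)
  truthRows <- vector("list", length(curveList))
  idx <- 0L
  for (i in seq_len(n)) {
    for (tp in tps) {
      pars <- cultivarPar[[i]]
      if (tp == tps[2]) pars <- pars * 2^cultivarShift[[i]]
      for (fr in seq_len(config@nFruit)) {
        fpars <- pars * exp(stats::rnorm(length(pars), 0, config@fruitCV))
        sim <- simulateMechanogram(as.list(fpars), cultivar = cvs[i],
                                   timepoint = tp, fruit = as.character(fr),
                                   strainStep = step,
                                   noiseSd = config@forceNoiseSd,
                                   acquisitionRate = config@acquisitionRate)
        idx <- idx + 1L
        curveList[[idx]] <- sim$curve
        truthRows[[idx]] <- data.frame(cultivar = cvs[i], timepoint = tp,
                                       fruit = as.character(fr),
                                       t(sim$truth))
      }
    }
  }
  curveTruth <- do.call(rbind, truthRows)

  ## ---- volatiles ---------------------------------------------------------
  vc <- config@vocClasses
  va <- config@vocArchetypes
  vocArch <- va$name[sample(nrow(va), n, replace = TRUE, prob = va$prob)]
  names(vocArch) <- cvs
  nmz <- nrow(vc)
  harvestMean <- matrix(0, n, nmz, dimnames = list(cvs, NULL))
  shiftMat <- matrix(0, n, nmz, dimnames = list(cvs, NULL))
  for (j in seq_len(nmz)) {
    harvestMean[, j] <- vc$harvest_mean[j] *
      stats::rlnorm(n, -config@vocCultivarSdLog^2 / 2, config@vocCultivarSdLog)
    mult <- if (vc$fermentation[j])
      va$multiplier[match(vocArch, va$name)] else rep(1, n)
    shiftMat[, j] <- vc$log2_shift[j] * mult +
      stats::rnorm(n, 0, config@vocShiftSd)
  }
  meta <- expand.grid(replicate = seq_len(config@nVocReplicates),
                      timepoint = tps, cultivar = cvs,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  meta <- meta[, c("cultivar", "timepoint", "replicate")]
  meta$is_blank <- FALSE
  blanks <- data.frame(cultivar = NA_character_, timepoint = NA_character_,
                       replicate = seq_len(config@nBlanks), is_blank = TRUE)
  meta <- rbind(meta, blanks)
  nSamp <- nrow(meta)
  conc <- matrix(0, nrow = nmz, ncol = nSamp)
  for (j in seq_len(nmz)) {
    mu <- ifelse(meta$is_blank, NA,
                 harvestMean[match(meta$cultivar, cvs), j] *
                   ifelse(meta$timepoint == tps[2],
                          2^shiftMat[match(meta$cultivar, cvs), j], 1))
    x <- numeric(nSamp)
    nb <- !meta$is_blank
    x[nb] <- .rlnormCV(sum(nb), mu[nb], config@vocReplicateCV)
    x[!nb] <- stats::rlnorm(sum(!nb), config@blankMeanLog, config@blankSdLog)
    conc[j, ] <- x
  }
  mzSignal <- vc$mz
  role <- rep("signal", nmz)
  parentOf <- rep(NA_real_, nmz)
  isoFactor <- rep(NA_real_, nmz)
  ## isotope channels: exact scalar multiples of a parent trait peak.
  ## parents are restricted to abundant channels so that parent * factor stays
  ## above the reporting floor (isotopologues are observed for strong peaks).
  if (config@nIsotopePeaks > 0) {
    nb <- !meta$is_blank
    rowMin <- apply(conc[, nb, drop = FALSE], 1, min)
    cand <- which(rowMin >= config@concFloor / 0.01)
    if (!length(cand)) cand <- order(rowMin, decreasing = TRUE)[1]
    parents <- cand[sample.int(length(cand), config@nIsotopePeaks,
                               replace = config@nIsotopePeaks > length(cand))]
    nthIso <- integer(length(mzSignal))
    for (k in seq_along(parents)) {
      fac <- stats::runif(1, 0.01, 0.2)
      row <- conc[parents[k], ] * fac
      if (config@isotopeNoiseSd > 0)
        row <- row * stats::rlnorm(nSamp, 0, config@isotopeNoiseSd)
      conc <- rbind(conc, row)
      ## repeated parents yield successive isotopologues (+1, +2, ... 13C)
      nthIso[parents[k]] <- nthIso[parents[k]] + 1L
      mzSignal <- c(mzSignal, vc$mz[parents[k]] + nthIso[parents[k]] * 1.00336)
      role <- c(role, "isotope")
      parentOf <- c(parentOf, vc$mz[parents[k]])
      isoFactor <- c(isoFactor, fac)
    }
  }
  ## pure-noise channels: same distribution as the blanks in every sample
  if (config@nNoisePeaks > 0) {
    noise <- matrix(stats::rlnorm(config@nNoisePeaks * nSamp,
                                  config@blankMeanLog, config@blankSdLog),
                    nrow = config@nNoisePeaks)
    conc <- rbind(conc, noise)
    repeat {
      cand <- round(stats::runif(config@nNoisePeaks, 30, 200), 3)
      if (!anyDuplicated(cand) && !any(cand %in% mzSignal)) break
    }
    mzSignal <- c(mzSignal, cand)
    role <- c(role, rep("noise", config@nNoisePeaks))
    parentOf <- c(parentOf, rep(NA_real_, config@nNoisePeaks))
    isoFactor <- c(isoFactor, rep(NA_real_, config@nNoisePeaks))
  }
  conc[conc < config@concFloor] <- config@concFloor
  peaks <- PeakTable(conc = conc, mz = mzSignal, sampleData = meta)

  ## ---- genetics ----------------------------------------------------------
  gen <- simulateGenotypes(cvs, nPopulations = config@nPopulations,
                           lociTable = config@lociTable,
                           hexaploidPops = config@hexaploidPops,
                           popProbs = config@popProbs,
                           popDivergence = config@popDivergence,
                           mutationGeomProb = config@mutationGeomProb)

  truth <- list(
    textureArchetype = archetype,
    textureParams = cultivarPar,
    textureShifts = cultivarShift,
    curveParams = curveTruth,
    vocArchetype = vocArch,
    vocClassOf = stats::setNames(vc$class, .mzName(vc$mz)),
    vocHarvestMean = harvestMean,
    vocShifts = shiftMat,
    vocPlantedShift = stats::setNames(vc$log2_shift, .mzName(vc$mz)),
    peakRole = data.frame(mz = mzSignal, role = role, parent_mz = parentOf,
                          isotope_factor = isoFactor),
    population = gen$population,
    seed = config@seed
  )
  new("Cohort", truth = truth, curves = new("MechCurveSet", curves = curveList),
      peaks = peaks, genotypes = gen$genotypes, config = config)
}

#' Construct a PeakTable
#'
#' @param conc numeric matrix, peaks (rows) x samples (columns), ug/kg.
#' @param mz numeric mass-to-charge value per row.
#' @param sampleData data.frame with columns `cultivar`, `timepoint`,
#'   `replicate`, `is_blank` (one row per sample).
#' @return a [PeakTable-class].
#' @export
PeakTable <- function(conc, mz, sampleData) {
  conc <- as.matrix(conc)
  rownames(conc) <- .mzName(mz)
  colnames(conc) <- sprintf("S%03d", seq_len(ncol(conc)))
  se <- SummarizedExperiment(
    assays = list(conc = conc),
    rowData = DataFrame(mz = as.numeric(mz)),
    colData = DataFrame(sampleData, row.names = colnames(conc)))
  new("PeakTable", se)
}
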