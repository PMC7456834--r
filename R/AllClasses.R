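#' @import methods
#' @importFrom S4Vectors DataFrame SimpleList
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData rowData
NULL

#' MechCurve: a single fruit compression profile
#'
#' One mechanogram: the force recorded while a cylindrical probe compresses a
#' berry to 90% deformation.  Strain is percent deformation (strictly
#' increasing, at most 100); force is in newtons (non-negative).
#'
#' @slot strain numeric, percent deformation, strictly increasing, >= 0.
#' @slot force numeric, newtons, same length as `strain`, >= 0.
#' @slot cultivar character(1) cultivar identifier.
#' @slot timepoint character(1), `"harvest"` or `"postharvest"`.
#' @slot fruit character(1) fruit identifier.
#' @slot acquisitionRate numeric(1), acquisition resolution in points per
#'   second (nominal 500).
#' @exportClass MechCurve
setClass("MechCurve",
  representation(
    strain = "numeric", force = "numeric",
    cultivar = "character", timepoint = "character", fruit = "character",
    acquisitionRate = "numeric"
  ),
  prototype(acquisitionRate = 500)
)

setValidity("MechCurve", function(object) {
  msg <- character()
  if (length(object@strain) != length(object@force))
    msg <- c(msg, "strain and force must have equal length")
  if (length(object@strain) < 10)
    msg <- c(msg, "curve must have at least 10 samples")
  if (length(object@strain) && any(diff(object@strain) <= 0))
    msg <- c(msg, "strain must be strictly increasing")
  if (length(object@strain) && (object@strain[1] < 0 ||
      max(object@strain) > 100))
    msg <- c(msg, "strain must lie in [0, 100]")
  if (length(object@force) && any(object@force < 0))
    msg <- c(msg, "force must be non-negative")
  if (length(msg)) msg else TRUE
})

#' MechCurveSet: a collection of mechanograms
#'
#' @slot curves list of [MechCurve-class] objects.
#' @exportClass MechCurveSet
setClass("MechCurveSet", representation(curves = "list"))

setValidity("MechCurveSet", function(object) {
  if (!all(vapply(object@curves, is, logical(1), "MechCurve")))
    return("all elements must be MechCurve objects")
  TRUE
})

#' PeakTable: samples x m/z concentration table
#'
#' A [SummarizedExperiment-class] holding one `conc` assay (rows = mass peaks,
#' columns = samples, values = concentration in ug/kg).  `rowData` carries the
#' `mz` value of each peak; `colData` carries `cultivar`, `timepoint`,
#' `replicate` and the logical `is_blank` flag used by the noise filter.
#'
#' @exportClass PeakTable
setClass("PeakTable", contains = "SummarizedExperiment")

setValidity("PeakTable", function(object) {
  msg <- character()
  if (!"conc" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'conc' is required")
  rd <- rowData(object)
  if (!"mz" %in% colnames(rd))
    msg <- c(msg, "rowData column 'mz' is required")
  else if (anyDuplicated(rd$mz))
    msg <- c(msg, "duplicate m/z values are not allowed")
  cd <- colData(object)
  need <- c("cultivar", "timepoint", "replicate", "is_blank")
  miss <- setdiff(need, colnames(cd))
  if (length(miss))
    msg <- c(msg, paste0("colData columns missing: ",
                         paste(miss, collapse = ", ")))
  if (!length(msg)) {
    conc <- assay(object, "conc")
    if (any(conc < 0)) msg <- c(msg, "concentrations must be non-negative")
    nb <- !cd$is_blank
    if (any(nb) && (anyNA(cd$cultivar[nb]) || anyNA(cd$timepoint[nb])))
      msg <- c(msg, "non-blank samples must carry cultivar and timepoint")
  }
  if (length(msg)) msg else TRUE
})

#' GenotypeTable: multilocus SSR genotypes with mixed ploidy
#'
#' Allele sizes are stored in base pairs per cultivar and locus; each locus has
#' a repeat length (bp per repeat unit) used to convert sizes to repeat units
#' for the stepwise-mutation distance.  Cultivars may be tetraploid or
#' hexaploid; loci may be missing (NULL) for a cultivar.
#'
#' @slot calls named list (cultivar) of named lists (locus) of numeric allele
#'   sizes in bp; between 1 and ploidy alleles per scored locus.
#' @slot ploidy named integer vector, 4 or 6 per cultivar.
#' @slot loci data.frame with columns `locus` and `repeat_bp`.
#' @exportClass GenotypeTable
setClass("GenotypeTable",
  representation(calls = "list", ploidy = "integer", loci = "data.frame"))

setValidity("GenotypeTable", function(object) {
  msg <- character()
  if (!all(c("locus", "repeat_bp") %in% colnames(object@loci)))
    msg <- c(msg, "loci must have columns locus, repeat_bp")
  else if (any(object@loci$repeat_bp < 1))
    msg <- c(msg, "repeat_bp must be >= 1")
  if (!setequal(names(object@calls), names(object@ploidy)))
    msg <- c(msg, "calls and ploidy must cover the same cultivars")
  if (!all(object@ploidy %in% c(4L, 6L)))
    msg <- c(msg, "ploidy must be 4 or 6")
  for (cv in names(object@calls)) {
    g <- object@calls[[cv]]
    if (!all(names(g) %in% object@loci$locus)) {
      msg <- c(msg, paste0("unknown locus for cultivar ", cv)); break
    }
    n <- vapply(g, length, integer(1))
    if (any(n < 1) || any(n > object@ploidy[[cv]])) {
      msg <- c(msg, paste0("cultivar ", cv,
                           ": allele count must be in 1..ploidy")); break
    }
  }
  if (length(msg)) msg else TRUE
})

#' CohortConfig: parameters of the synthetic germplasm cohort
#'
#' Defines the study design the generator emulates: cultivar and replicate
#' counts, the two assessment timepoints, texture archetypes with their
#' storage-shift vectors, volatile classes with planted log2 storage
#' trajectories, nuisance peaks (blank-equivalent noise, isotopes), and the
#' genetic population structure.  See [cohortConfig()] for defaults.
#'
#' @slot nCultivars integer(1), cultivars in the collection (default 46).
#' @slot nFruit integer(1), fruit measured per cultivar x timepoint.
#' @slot nVocReplicates integer(1), headspace replicates per cultivar x timepoint.
#' @slot nBlanks integer(1), blank headspace samples (>= 2).
#' @slot timepoints character(2), assessment labels.
#' @slot textureArchetypes data.frame of archetype means, spread and log2
#'   storage shifts (one row per archetype, see [defaultTextureArchetypes()]).
#' @slot archetypeProbs numeric, sampling weights of the archetypes.
#' @slot cultivarCV numeric(1), lognormal between-cultivar spread of texture
#'   parameters (sd of log).
#' @slot fruitCV numeric(1), lognormal fruit-to-fruit spread within cultivar.
#' @slot forceNoiseSd numeric(1), gaussian force noise as a fraction of peak
#'   force (0 gives exact piecewise-linear curves).
#' @slot textureShiftSd numeric(1), per-cultivar sd (log2) around the planted
#'   texture storage shifts.
#' @slot strainStep numeric(1), strain grid spacing in percent; NA derives it
#'   from test speed, fruit diameter and acquisition rate.
#' @slot testSpeed numeric(1), compression speed, mm/min.
#' @slot fruitDiameter numeric(1), nominal berry diameter, mm.
#' @slot acquisitionRate numeric(1), points per second.
#' @slot vocClasses data.frame of volatile classes (class, mz, harvest mean,
#'   log2 storage shift, directional flag), see [defaultVocClasses()].
#' @slot vocArchetypes data.frame of storage-response archetypes
#'   (name, shift multiplier, probability).
#' @slot vocCultivarSdLog numeric(1), between-cultivar lognormal sd of harvest
#'   concentrations.
#' @slot vocReplicateCV numeric(1), replicate-level CV (> 0).
#' @slot vocShiftSd numeric(1), per-cultivar sd (log2) around the planted
#'   class storage shift.
#' @slot blankMeanLog numeric(1), mean log concentration of blank channels.
#' @slot blankSdLog numeric(1), sd of log blank concentrations.
#' @slot nIsotopePeaks integer(1), isotope peaks planted as exact scalar
#'   multiples of parent peaks.
#' @slot isotopeNoiseSd numeric(1), multiplicative lognormal noise applied to
#'   isotope channels (0 keeps them exact scalar multiples).
#' @slot nNoisePeaks integer(1), pure-noise peaks drawn from the blank
#'   distribution.
#' @slot concFloor numeric(1), trace-level reporting floor, ug/kg.
#' @slot nPopulations integer(1), planted genetic populations K.
#' @slot lociTable data.frame with columns locus, repeat_bp, tail.
#' @slot hexaploidPops integer, indices of populations simulated as hexaploid.
#' @slot popProbs numeric, population sampling weights.
#' @slot popDivergence numeric(1), scale (repeat units) of modal-allele
#'   separation between populations.
#' @slot mutationGeomProb numeric(1), geometric-tail parameter of stepwise
#'   allele offsets around the population mode.
#' @slot seed integer(1) base RNG seed.
#' @exportClass CohortConfig
setClass("CohortConfig",
  representation(
    nCultivars = "integer", nFruit = "integer", nVocReplicates = "integer",
    nBlanks = "integer", timepoints = "character",
    textureArchetypes = "data.frame", archetypeProbs = "numeric",
    cultivarCV = "numeric", fruitCV = "numeric", forceNoiseSd = "numeric",
    textureShiftSd = "numeric",
    strainStep = "numeric", testSpeed = "numeric", fruitDiameter = "numeric",
    acquisitionRate = "numeric",
    vocClasses = "data.frame", vocArchetypes = "data.frame",
    vocCultivarSdLog = "numeric", vocReplicateCV = "numeric",
    vocShiftSd = "numeric", blankMeanLog = "numeric", blankSdLog = "numeric",
    nIsotopePeaks = "integer", isotopeNoiseSd = "numeric",
    nNoisePeaks = "integer", concFloor = "numeric",
    nPopulations = "integer", lociTable = "data.frame",
    hexaploidPops = "integer", popProbs = "numeric",
    popDivergence = "numeric", mutationGeomProb = "numeric",
    seed = "integer"
  )
)

setValidity("CohortConfig", function(object) {
  msg <- character()
  chkCount <- function(x, nm) {
    if (length(x) != 1 || is.na(x) || x < 1)
      msg <<- c(msg, paste0(nm, " must be a count >= 1"))
  }
  chkCount(object@nCultivars, "nCultivars")
  chkCount(object@nFruit, "nFruit")
  chkCount(object@nVocReplicates, "nVocReplicates")
  chkCount(object@nBlanks, "nBlanks")
  chkCount(object@nPopulations, "nPopulations")
  if (length(object@timepoints) != 2)
    msg <- c(msg, "timepoints must have exactly two labels")
  if (object@vocReplicateCV <= 0 || object@cultivarCV < 0 ||
      object@fruitCV < 0)
    msg <- c(msg, "CVs must be positive (vocReplicateCV strictly)")
  if (nrow(object@textureArchetypes) < 1)
    msg <- c(msg, "textureArchetypes must have at least one archetype")
  if (length(object@archetypeProbs) != nrow(object@textureArchetypes) ||
      any(object@archetypeProbs < 0) || sum(object@archetypeProbs) <= 0)
    msg <- c(msg, "archetypeProbs must be non-negative weights, one per archetype")
  if (nrow(object@vocClasses) < 1)
    msg <- c(msg, "vocClasses must have at least one trait")
  if (anyDuplicated(object@vocClasses$mz))
    msg <- c(msg, "vocClasses m/z values must be unique")
  if (length(object@popProbs) != object@nPopulations ||
      any(object@popProbs < 0) || sum(object@popProbs) <= 0)
    msg <- c(msg, "popProbs must be non-negative weights, one per population")
  if (any(!object@hexaploidPops %in% seq_len(object@nPopulations)))
    msg <- c(msg, "hexaploidPops must index populations 1..K")
  if (!all(c("locus", "repeat_bp", "tail") %in% colnames(object@lociTable)))
    msg <- c(msg, "lociTable must have columns locus, repeat_bp, tail")
  if (object@nIsotopePeaks < 0 || object@nNoisePeaks < 0)
    msg <- c(msg, "nIsotopePeaks/nNoisePeaks must be >= 0")
  if (object@concFloor <= 0) msg <- c(msg, "concFloor must be > 0")
  if (object@mutationGeomProb <= 0 || object@mutationGeomProb > 1)
    msg <- c(msg, "mutationGeomProb must be in (0, 1]")
  if (length(msg)) msg else TRUE
})

#' Cohort: a simulated germplasm collection with ground truth
#'
#' @slot truth list of planted ground truth (archetype labels, per-fruit curve
#'   parameters, volatile class membership and shifts, populations of origin).
#' @slot curves [MechCurveSet-class].
#' @slot peaks [PeakTable-class].
#' @slot genotypes [GenotypeTable-class].
#' @slot config [CohortConfig-class] that generated the cohort.
#' @exportClass Cohort
setClass("Cohort",
  representation(truth = "list", curves = "MechCurveSet",
                 peaks = "PeakTable", genotypes = "GenotypeTable",
                 config = "CohortConfig"))

#' PCAResult: principal component decomposition of a trait matrix
#'
#' @slot scores matrix, cultivars x components.
#' @slot loadings matrix, traits x components, orthonormal columns.
#' @slot varExplained numeric, variance fraction per component.
#' @exportClass PCAResult
setClass("PCAResult",
  representation(scores = "matrix", loadings = "matrix",
                 varExplained = "numeric"))

setValidity("PCAResult", function(object) {
  msg <- character()
  v <- object@varExplained
  if (any(v < -1e-12) || any(v > 1 + 1e-12))
    msg <- c(msg, "variance fractions must lie in [0, 1]")
  if (length(v) > 1 && any(diff(v) > 1e-8))
    msg <- c(msg, "variance fractions must be non-increasing")
  if (sum(v) > 1 + 1e-8)
    msg <- c(msg, "variance fractions must sum to at most 1")
  if (length(msg)) msg else TRUE
})

#' ClusterResult: hierarchical clustering of cultivars
#'
#' @slot labels named integer cluster labels in 1..k.
#' @slot k integer(1), number of clusters cut.
#' @slot heights numeric, non-decreasing Ward merge heights.
#' @slot method character(1) method tag (`"ward-euclidean"`).
#' @slot hclust the full `stats::hclust` merge history.
#' @slot lowConfidence logical(1), TRUE when the cluster-count criterion was
#'   flat and the documented default was returned.
#' @exportClass ClusterResult
setClass("ClusterResult",
  representation(labels = "integer", k = "integer", heights = "numeric",
                 method = "character", hclust = "ANY",
                 lowConfidence = "logical"),
  prototype(lowConfidence = FALSE))

setValidity("ClusterResult", function(object) {
  msg <- character()
  if (length(object@labels) &&
      !all(object@labels %in% seq_len(object@k)))
    msg <- c(msg, "labels must lie in 1..k")
  if (length(object@heights) > 1 && any(diff(object@heights) < -1e-8))
    msg <- c(msg, "merge heights must be non-decreasing")
  if (length(msg)) msg else TRUE
})

#' DAPCResult: genetic clustering by discriminant analysis of principal components
#'
#' @slot bic numeric, BIC value per K = 1..kMax.
#' @slot k integer(1), selected K (argmin BIC).
#' @slot nPC integer(1), principal components retained for the discriminant step.
#' @slot assignments named integer hard cluster assignments.
#' @slot posterior matrix, cultivars x K posterior memberships (rows sum to 1).
#' @slot discriminant matrix, discriminant axis scores (cultivars x axes).
#' @exportClass DAPCResult
setClass("DAPCResult",
  representation(bic = "numeric", k = "integer", nPC = "integer",
                 assignments = "integer", posterior = "matrix",
                 discriminant = "matrix"))

setValidity("DAPCResult", function(object) {
  msg <- character()
  if (which.min(object@bic) != object@k)
    msg <- c(msg, "selected K must minimise BIC")
  if (nrow(object@posterior) &&
      any(abs(rowSums(object@posterior) - 1) > 1e-9))
    msg <- c(msg, "posterior rows must sum to 1")
  if (length(msg)) msg else TRUE
})
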