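#' @include AllClasses.R
NULL

#' Accessors for berryroad classes
#'
#' `curves()` returns the list of [MechCurve-class] objects in a set;
#' `mzValues()` the mass-peak values of a [PeakTable-class];
#' `cultivarNames()` the cultivar identifiers of a container;
#' `clusterLabels()` the hard assignments of a clustering result.
#'
#' @param x a berryroad object.
#' @return see details per class.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("curves", function(x) standardGeneric("curves"))

#' @rdname accessors
#' @export
setGeneric("mzValues", function(x) standardGeneric("mzValues"))

#' @rdname accessors
#' @export
setGeneric("cultivarNames", function(x) standardGeneric("cultivarNames"))

#' @rdname accessors
#' @export
setGeneric("clusterLabels", function(x) standardGeneric("clusterLabels"))

#' @rdname accessors
setMethod("curves", "MechCurveSet", function(x) x@curves)

#' @rdname accessors
setMethod("curves", "Cohort", function(x) x@curves@curves)

#' @rdname accessors
setMethod("mzValues", "PeakTable", function(x) rowData(x)$mz)

#' @rdname accessors
setMethod("cultivarNames", "GenotypeTable", function(x) names(x@calls))

#' @rdname accessors
setMethod("cultivarNames", "Cohort",
          function(x) names(x@truth$textureArchetype))

#' @rdname accessors
setMethod("clusterLabels", "ClusterResult", function(x) x@labels)

#' @rdname accessors
setMethod("clusterLabels", "DAPCResult", function(x) x@assignments)

setMethod("show", "MechCurve", function(object) {
  cat(sprintf("MechCurve: %s / %s / fruit %s, %d points, strain %.1f-%.1f%%, peak force %.2f N\n",
              object@cultivar, object@timepoint, object@fruit,
              length(object@strain), min(object@strain), max(object@strain),
              max(object@force)))
})

setMethod("show", "MechCurveSet", function(object) {
  cat(sprintf("MechCurveSet with %d curves\n", length(object@curves)))
})

setMethod("show", "GenotypeTable", function(object) {
  cat(sprintf("GenotypeTable: %d cultivars (%d tetraploid, %d hexaploid), %d loci\n",
              length(object@calls), sum(object@ploidy == 4L),
              sum(object@ploidy == 6L), nrow(object@loci)))
})

setMethod("show", "Cohort", function(object) {
  cat(sprintf("Cohort: %d cultivars x {%s}\n", object@config@nCultivars,
              paste(object@config@timepoints, collapse = ", ")))
  cat(sprintf("  curves:    %d mechanograms\n", length(object@curves@curves)))
  cat(sprintf("  peaks:     %d m/z x %d samples (%d blanks)\n",
              nrow(object@peaks), ncol(object@peaks),
              sum(colData(object@peaks)$is_blank)))
  cat(sprintf("  genotypes: %d cultivars, %d loci, %d planted populations\n",
              length(object@genotypes@calls), nrow(object@genotypes@loci),
              object@config@nPopulations))
})

setMethod("show", "PCAResult", function(object) {
  v <- round(100 * object@varExplained[seq_len(min(3, length(object@varExplained)))])
  cat(sprintf("PCAResult: %d x %d scores; variance explained %s%%\n",
              nrow(object@scores), ncol(object@scores),
              paste(v, collapse = "/")))
})

setMethod("show", "ClusterResult", function(object) {
  cat(sprintf("ClusterResult (%s): %d observations in %d clusters%s\n",
              object@method, length(object@labels), object@k,
              if (object@lowConfidence) " [low confidence]" else ""))
})

setMethod("show", "DAPCResult", function(object) {
  cat(sprintf("DAPCResult: K = %d selected by BIC over 1..%d, %d PCs retained\n",
              object@k, length(object@bic), object@nPC))
})
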