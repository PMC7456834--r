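#' @include AllClasses.R
NULL

#' Storage index: log2 ratio of postharvest to harvest trait values
#'
#' `SI = log2(q_post / q_harvest)`.  Positive values indicate enhancement of
#' the trait during storage, negative values a loss.  Values below `floor`
#' are replaced by the floor before the ratio (trace-level reporting);
#' non-finite or non-positive inputs after flooring yield `NA` with a message
#' naming the offending entries when names are available.
#'
#' @param qHarvest,qPost numeric vectors or matrices of trait values measured
#'   at harvest and after storage (recycled like arithmetic operands).
#' @param floor positive reporting floor substituted for smaller values.
#' @return numeric of the common shape, the storage index in log2 units.
#' @examples
#' storageIndex(4, 8)                      # +1: trait doubled
#' storageIndex(2228.26, 3956.04)          # ~0.828
#' storageIndex(c(a = 1, b = 2), c(2, 2))  # per-trait
#' @export
storageIndex <- function(qHarvest, qPost, floor = 1e-3) {
  if (floor <= 0) stop("floor must be positive")
  h <- pmax(qHarvest, floor)
  p <- pmax(qPost, floor)
  bad <- !is.finite(h) | !is.finite(p)
  if (any(bad)) {
    nm <- names(qHarvest)
    message("storage index undefined for ", sum(bad), " entr(y/ies)",
            if (!is.null(nm)) paste0(": ", paste(nm[bad], collapse = ", ")))
  }
  si <- log2(p / h)
  si[bad] <- NA_real_
  si
}

#' Storage-index matrix from harvest and postharvest trait matrices
#'
#' Rows are cultivars, columns traits (texture parameters or mass peaks).
#' The SI is computed on cultivar means (aggregation over replicates is the
#' caller's responsibility, see [summarizeTexture()] and
#' [cultivarMeanMatrix()]); cultivars missing from either matrix get `NA`
#' rows.
#'
#' @param harvest,post numeric matrices with cultivar rownames and identical
#'   trait columns.
#' @param floor reporting floor, see [storageIndex()].
#' @return matrix of storage indices, cultivars x traits.
#' @export
siMatrix <- function(harvest, post, floor = 1e-3) {
  if (!identical(colnames(harvest), colnames(post)))
    stop("harvest and post matrices must share trait columns")
  cvs <- union(rownames(harvest), rownames(post))
  out <- matrix(NA_real_, length(cvs), ncol(harvest),
                dimnames = list(cvs, colnames(harvest)))
  common <- intersect(rownames(harvest), rownames(post))
  if (length(common))
    out[common, ] <- storageIndex(harvest[common, , drop = FALSE],
                                  post[common, , drop = FALSE], floor = floor)
  out
}

#' Per-trait summary of a storage-index matrix
#'
#' Reports minimum, maximum and mean SI across cultivars for every trait,
#' excluding missing entries; traits with no non-missing cultivar are dropped
#' with a warning.
#'
#' @param si matrix of storage indices (cultivars x traits).
#' @return data.frame with columns `trait`, `min`, `max`, `mean`,
#'   `n_missing`.
#' @export
siSummary <- function(si) {
  keep <- colSums(!is.na(si)) > 0
  if (any(!keep))
    warning("dropping trait(s) with no non-missing SI: ",
            paste(colnames(si)[!keep], collapse = ", "))
  si <- si[, keep, drop = FALSE]
  data.frame(
    trait = colnames(si),
    min = apply(si, 2, min, na.rm = TRUE),
    max = apply(si, 2, max, na.rm = TRUE),
    mean = colMeans(si, na.rm = TRUE),
    n_missing = colSums(is.na(si)),
    row.names = NULL)
}

#' Cultivar-mean trait matrix from a peak table
#'
#' Averages replicate concentrations per cultivar at one timepoint, returning
#' the cultivar x m/z matrix downstream multivariate and SI steps consume.
#'
#' @param table a [PeakTable-class].
#' @param timepoint timepoint label to select.
#' @return numeric matrix, cultivars x peaks (columns named `mz_<value>`).
#' @export
cultivarMeanMatrix <- function(table, timepoint) {
  cd <- colData(table)
  sel <- !cd$is_blank & cd$timepoint == timepoint
  if (!any(sel)) stop("no samples at timepoint ", timepoint)
  conc <- assay(table, "conc")[, sel, drop = FALSE]
  cv <- factor(cd$cultivar[sel])
  ## average replicates: apply over peak rows gives cultivars x peaks
  m <- apply(conc, 1, function(x) tapply(x, cv, mean))
  if (is.null(dim(m))) m <- matrix(m, nrow = 1)   # single cultivar
  rownames(m) <- levels(cv)
  colnames(m) <- rownames(conc)
  m
}
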