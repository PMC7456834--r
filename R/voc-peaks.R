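#' @include AllClasses.R
NULL

## Welch one-sided test of non-blank > blank on log concentrations.
## Degenerate (zero-variance-everywhere) peaks get p = 1: no evidence of signal.
.welchOneSided <- function(x, y) {
  if (stats::sd(x) < 1e-12 && stats::sd(y) < 1e-12) {
    return(list(statistic = 0, p.value = 1))
  }
  tt <- tryCatch(stats::t.test(x, y, alternative = "greater",
                               var.equal = FALSE),
                 error = function(e) NULL)
  if (is.null(tt)) return(list(statistic = 0, p.value = 1))
  list(statistic = unname(tt$statistic), p.value = tt$p.value)
}

#' Blank-based noise filter
#'
#' For each mass peak, tests whether fruit samples exceed the blank samples:
#' Welch's unequal-variance t test, one-sided (non-blank mean > blank mean),
#' on log-transformed concentrations (`log(conc + floor)`).  Peaks with
#' p >= `alpha` are flagged as noise.  No multiplicity correction is applied
#' by default; set `adjust` to a `p.adjust` method to enable one.
#'
#' @param table a [PeakTable-class] with at least 2 blank and 2 fruit samples.
#' @param alpha significance level (default 0.05).
#' @param floor additive floor before the log transform.
#' @param adjust `"none"` (default) or a [stats::p.adjust()] method.
#' @return data.frame, one row per m/z: `mz`, `statistic`, `p`, `retained`.
#' @export
noiseFilter <- function(table, alpha = 0.05, floor = 1e-3, adjust = "none") {
  cd <- colData(table)
  if (sum(cd$is_blank) < 2)
    stop("noise filtering requires at least 2 blank samples; supply blanks")
  if (sum(!cd$is_blank) < 2)
    stop("noise filtering requires at least 2 non-blank samples")
  conc <- log(assay(table, "conc") + floor)
  bl <- which(cd$is_blank); nb <- which(!cd$is_blank)
  res <- t(vapply(seq_len(nrow(conc)), function(i) {
    w <- .welchOneSided(conc[i, nb], conc[i, bl])
    c(w$statistic, w$p.value)
  }, numeric(2)))
  p <- res[, 2]
  if (adjust != "none") p <- stats::p.adjust(p, method = adjust)
  data.frame(mz = mzValues(table), statistic = res[, 1], p = p,
             retained = p < alpha, test = "welch-one-sided-log")
}

#' Isotope / correlation filter
#'
#' Builds a graph on peaks with an edge wherever the product-moment
#' correlation of log concentrations exceeds `threshold` (strictly), then
#' retains exactly one representative per connected component: the peak with
#' the lowest m/z (monoisotopic parents are lighter than their isotopologues),
#' ties broken by higher mean concentration.  Correlations are computed over
#' fruit (non-blank) samples when blanks are present; constant peaks have
#' undefined correlation and are treated as uncorrelated (a message reports
#' them).
#'
#' @param table a [PeakTable-class] with at least 3 usable samples.
#' @param threshold correlation threshold; removal requires r > threshold.
#' @param floor additive floor before the log transform.
#' @return data.frame, one row per m/z: `mz`, `retained`, `partner_mz` (the
#'   retained representative for removed peaks), `max_correlation`.
#' @export
correlationFilter <- function(table, threshold = 0.99, floor = 1e-3) {
  cd <- colData(table)
  use <- if (any(!cd$is_blank)) which(!cd$is_blank) else seq_len(ncol(table))
  if (length(use) < 3)
    stop("correlation filtering requires at least 3 samples")
  lc <- t(log(assay(table, "conc")[, use, drop = FALSE] + floor))
  mz <- mzValues(table)
  n <- ncol(lc)
  sds <- apply(lc, 2, stats::sd)
  const <- sds < 1e-12
  if (any(const))
    message(sum(const), " constant peak(s) with undefined correlation ",
            "treated as uncorrelated")
  cm <- matrix(0, n, n)
  if (sum(!const) >= 2)
    cm[!const, !const] <- stats::cor(lc[, !const, drop = FALSE])
  diag(cm) <- 0
  adj <- cm > threshold
  gr <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(gr)$membership
  meanConc <- colMeans(exp(lc))
  retained <- logical(n)
  partner <- rep(NA_real_, n)
  for (cc in unique(comp)) {
    members <- which(comp == cc)
    ## representative: lowest m/z, ties by higher mean concentration
    o <- order(mz[members], -meanConc[members])
    rep_ <- members[o[1]]
    retained[rep_] <- TRUE
    partner[setdiff(members, rep_)] <- mz[rep_]
  }
  maxCor <- apply(cm, 1, max)
  data.frame(mz = mz, retained = retained, partner_mz = partner,
             max_correlation = maxCor)
}

#' Reduce a peak table by the noise and correlation filters
#'
#' Applies the blank-based noise filter first, then the isotope/correlation
#' filter on the survivors (the documented, order-sensitive convention).  The
#' reduced table is restricted to retained peaks with blank samples dropped.
#'
#' @param table a [PeakTable-class].
#' @param alpha noise-filter significance level.
#' @param threshold correlation threshold.
#' @param floor additive floor used by both filters.
#' @return list with `table` (reduced [PeakTable-class]) and `report` (list
#'   with `retained`, `removed_noise`, `removed_correlated` data.frames whose
#'   m/z sets partition the input).
#' @examples
#' co <- simulateCohort(cohortConfig(nCultivars = 4, nFruit = 1, seed = 2))
#' red <- reducePeaks(co@peaks)
#' nrow(red$table)
#' @export
reducePeaks <- function(table, alpha = 0.05, threshold = 0.99, floor = 1e-3) {
  nf <- noiseFilter(table, alpha = alpha, floor = floor)
  keep1 <- which(nf$retained)
  sub <- table[keep1, ]
  cf <- correlationFilter(sub, threshold = threshold, floor = floor)
  keep2 <- keep1[cf$retained]
  cd <- colData(table)
  reduced <- table[keep2, !cd$is_blank]
  report <- list(
    retained = data.frame(mz = mzValues(table)[keep2]),
    removed_noise = nf[!nf$retained, c("mz", "statistic", "p")],
    removed_correlated = cf[!cf$retained,
                            c("mz", "partner_mz", "max_correlation")]
  )
  rownames(report$removed_noise) <- NULL
  rownames(report$removed_correlated) <- NULL
  list(table = reduced, report = report)
}

#' Annotate mass peaks against the packaged identification library
#'
#' Matches each query m/z to the nearest entry of the packaged PTR-ToF-MS
#' annotation library (tentative identities from GC-MS comparison) within a
#' tolerance; unmatched peaks are annotated as unknown.
#'
#' @param mz numeric vector of mass peaks.
#' @param tolerance maximum |query - library| m/z difference (default 0.005).
#' @param library optional data.frame with columns `mz`, `formula`,
#'   `identification`; defaults to the packaged table.
#' @return data.frame with columns `mz`, `library_mz`, `formula`,
#'   `identification` (`"unknown"` when unmatched).
#' @examples
#' annotatePeaks(c(33.033, 47.043, 999.999))$identification
#' @export
annotatePeaks <- function(mz, tolerance = 0.005, library = NULL) {
  if (is.null(library)) {
    path <- system.file("extdata", "ptr_tof_annotation.tsv",
                        package = "berryroad", mustWork = TRUE)
    library <- utils::read.delim(path, colClasses = c("numeric", "character",
                                                      "character"))
  }
  out <- data.frame(mz = mz, library_mz = NA_real_,
                    formula = NA_character_,
                    identification = "unknown")
  for (i in seq_along(mz)) {
    d <- abs(library$mz - mz[i])
    j <- which.min(d)
    if (length(j) && d[j] <= tolerance) {
      out$library_mz[i] <- library$mz[j]
      out$formula[i] <- library$formula[j]
      out$identification[i] <-
        if (nzchar(library$identification[j])) library$identification[j]
        else "unknown"
    }
  }
  out
}
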