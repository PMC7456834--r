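#' @include AllClasses.R
NULL

#' Prepare a trait matrix for multivariate analysis
#'
#' Traits mix units (N, %, N/%, ug/kg), so columns are centred and scaled to
#' unit variance by default.  Volatile matrices are log10-transformed (after
#' flooring) before standardization because concentrations span several orders
#' of magnitude; texture matrices are not.  Missing cells are imputed by the
#' trait median (a message reports the count); zero-variance columns are
#' dropped with a warning when scaling.
#'
#' @param m numeric matrix, cultivars x traits.
#' @param type `"texture"` or `"voc"` (controls the log transform).
#' @param scale centre/scale columns (default TRUE).
#' @param floor flooring applied before log10 for `type = "voc"`.
#' @return numeric matrix ready for [pcaTraits()] / [wardCluster()].
#' @export
buildTraitMatrix <- function(m, type = c("texture", "voc"), scale = TRUE,
                             floor = 1e-3) {
  type <- match.arg(type)
  m <- as.matrix(m)
  if (type == "voc") m <- log10(pmax(m, floor))
  nmiss <- sum(is.na(m))
  if (nmiss > 0) {
    message("imputing ", nmiss, " missing cell(s) by trait median")
    for (j in seq_len(ncol(m))) {
      bad <- is.na(m[, j])
      if (any(bad)) m[bad, j] <- stats::median(m[, j], na.rm = TRUE)
    }
  }
  if (scale) {
    v <- apply(m, 2, stats::var)
    drop <- v <= 0 | !is.finite(v)
    if (any(drop)) {
      warning("dropping zero-variance column(s): ",
              paste(colnames(m)[drop], collapse = ", "))
      m <- m[, !drop, drop = FALSE]
    }
    m <- base::scale(m)
    attr(m, "scaled:center") <- NULL
    attr(m, "scaled:scale") <- NULL
  }
  m
}

#' Principal component analysis of a trait matrix
#'
#' Centred (and optionally unit-scaled) PCA.  Component signs are fixed by
#' making the largest-magnitude loading of each component positive, so the
#' decomposition is deterministic.
#'
#' @param m numeric matrix, cultivars x traits (rows >= 2, columns >= 2).
#' @param scale centre/scale columns before the decomposition.
#' @return a [PCAResult-class].
#' @examples
#' m <- matrix(rnorm(40), 10, 4)
#' pcaTraits(m)@varExplained
#' @export
pcaTraits <- function(m, scale = TRUE) {
  m <- as.matrix(m)
  if (nrow(m) < 2 || ncol(m) < 2)
    stop("PCA requires at least 2 rows and 2 columns")
  if (scale) {
    v <- apply(m, 2, stats::var)
    drop <- v <= 0 | !is.finite(v)
    if (any(drop)) {
      warning("dropping zero-variance column(s) before scaled PCA: ",
              paste(colnames(m)[drop], collapse = ", "))
      m <- m[, !drop, drop = FALSE]
    }
  }
  pc <- stats::prcomp(m, center = TRUE, scale. = scale)
  ## deterministic sign: largest-magnitude loading positive per component
  for (j in seq_len(ncol(pc$rotation))) {
    i <- which.max(abs(pc$rotation[, j]))
    if (pc$rotation[i, j] < 0) {
      pc$rotation[, j] <- -pc$rotation[, j]
      pc$x[, j] <- -pc$x[, j]
    }
  }
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  new("PCAResult", scores = pc$x, loadings = pc$rotation,
      varExplained = ve[seq_len(ncol(pc$x))])
}

#' Ward hierarchical clustering of cultivars
#'
#' Agglomerative clustering with the Ward criterion on Euclidean distances of
#' the (already prepared) trait matrix.  When `k` is omitted the cut is chosen
#' by [chooseK()].
#'
#' @param m numeric matrix, cultivars x traits.
#' @param k number of clusters; `NULL` selects it by the inertia-jump rule.
#' @param kMax search ceiling passed to [chooseK()].
#' @return a [ClusterResult-class] (full merge history retained in `@hclust`).
#' @export
wardCluster <- function(m, k = NULL, kMax = 10) {
  m <- as.matrix(m)
  n <- nrow(m)
  if (n < 2) stop("clustering requires at least 2 observations")
  if (!is.null(k) && k > n)
    stop("k (", k, ") cannot exceed the number of observations (", n, ")")
  hc <- stats::hclust(stats::dist(m, method = "euclidean"),
                      method = "ward.D2")
  lowConf <- FALSE
  if (is.null(k)) {
    sel <- chooseK(hc, m, kMax = kMax)
    k <- sel$k
    lowConf <- sel$lowConfidence
  }
  labels <- stats::setNames(as.integer(stats::cutree(hc, k = k)),
                            rownames(m))
  new("ClusterResult", labels = labels, k = as.integer(k),
      heights = hc$height, method = "ward-euclidean", hclust = hc,
      lowConfidence = lowConf)
}

## total within-cluster sum of squares for a given flat cut
.withinSS <- function(m, labels) {
  sum(vapply(unique(labels), function(l) {
    x <- m[labels == l, , drop = FALSE]
    sum(sweep(x, 2, colMeans(x))^2)
  }, numeric(1)))
}

#' Select the number of clusters by the inertia-jump rule
#'
#' Computes the within-cluster inertia W(k) for cuts k = 1..kMax+1 and selects
#' the K maximizing the relative loss between successive cuts,
#' `(W(K-1) - W(K)) / (W(K) - W(K+1))`: a sharp elbow where one further split
#' stops paying.  When the criterion is flat (maximum jump below
#' `flatThreshold`) the documented default K = 2 is returned with a
#' low-confidence flag.
#'
#' @param hc an `hclust` object (Ward merge history).
#' @param m the matrix the clustering was computed on.
#' @param kMax largest K considered (default 10).
#' @param flatThreshold jump ratio below which the criterion is called flat.
#' @return list with `k`, `lowConfidence`, and the `jump` profile.
#' @export
chooseK <- function(hc, m, kMax = 10, flatThreshold = 3) {
  n <- nrow(m)
  kMax <- min(kMax, n - 1)
  if (kMax < 2) return(list(k = min(2L, n), lowConfidence = TRUE,
                            jump = numeric(0)))
  W <- vapply(seq_len(kMax + 1), function(k)
    .withinSS(m, stats::cutree(hc, k = min(k, n))), numeric(1))
  tot <- W[1]
  eps <- 1e-12 * max(tot, 1)
  ks <- 2:kMax
  jump <- (W[ks - 1] - W[ks]) / pmax(W[ks] - W[ks + 1], eps)
  names(jump) <- ks
  if (max(jump) < flatThreshold)
    return(list(k = 2L, lowConfidence = TRUE, jump = jump))
  list(k = as.integer(ks[which.max(jump)]), lowConfidence = FALSE,
       jump = jump)
}

#' Agreement between two cultivar partitions
#'
#' Adjusted Rand index plus a permutation p-value:
#' `p = (1 + #\{permuted ARI >= observed\}) / (nPerm + 1)` under random
#' relabelling of the second partition.
#'
#' @param labelsA,labelsB named label vectors over the same cultivar set.
#' @param nPerm number of permutations (>= 99).
#' @param seed RNG seed for the permutations.
#' @return list with `ari` and `p`.
#' @examples
#' a <- c(x = 1, y = 1, z = 2, w = 2)
#' clusterAssociation(a, a, nPerm = 99)$ari   # 1
#' @export
clusterAssociation <- function(labelsA, labelsB, nPerm = 999, seed = 1) {
  if (is.null(names(labelsA)) || is.null(names(labelsB)))
    stop("labelings must be named by cultivar")
  if (!setequal(names(labelsA), names(labelsB)))
    stop("labelings must cover the same cultivar set")
  if (nPerm < 99) stop("nPerm must be at least 99")
  labelsB <- labelsB[names(labelsA)]
  obs <- mclust::adjustedRandIndex(labelsA, labelsB)
  set.seed(seed)
  exceed <- 0L
  for (i in seq_len(nPerm)) {
    if (mclust::adjustedRandIndex(labelsA, sample(labelsB)) >= obs)
      exceed <- exceed + 1L
  }
  list(ari = obs, p = (1 + exceed) / (nPerm + 1))
}
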