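#' @include AllClasses.R
NULL

## universal primer tails attached to locus-specific forward primers;
## reported allele sizes are corrected by the tail length
.UNIVERSAL_TAILS <- c(
  T7        = "TAATACGACTCACTATAGGG",
  M13       = "TGTAAAACGACGGCCAGT",
  M13R      = "CAGGAAACAGCTATGACC",
  D12S1090f = "CTATAGGGCACGCGTGGT"
)

#' Correct raw allele sizes for the universal-tail length
#'
#' Fragment sizes called from capillary electrophoresis include the 5'
#' universal tail carried by the forward primer; the true allele size is the
#' raw size minus the tail length (T7: 20 nt; M13, M13R, D12S1090f: 18 nt).
#'
#' @param sizes numeric raw fragment sizes, bp.
#' @param tail tail label, one of `"T7"`, `"M13"`, `"M13R"`, `"D12S1090f"`.
#' @return numeric corrected sizes.
#' @examples
#' adjustAlleleSizes(220, "T7")   # 200
#' adjustAlleleSizes(150, "M13")  # 132
#' @export
adjustAlleleSizes <- function(sizes, tail) {
  if (length(tail) != 1 || !tail %in% names(.UNIVERSAL_TAILS))
    stop("unknown universal tail '", tail, "'; known tails: ",
         paste(names(.UNIVERSAL_TAILS), collapse = ", "))
  sizes - nchar(.UNIVERSAL_TAILS[[tail]])
}

## per-allele stepwise-mutation distance in repeat units
.bruvoAllele <- function(x) 1 - 2^(-abs(x))

## memoized permutation matrices (rows = permutations of 1..p)
.permCache <- new.env(parent = emptyenv())
.permutations <- function(p) {
  key <- as.character(p)
  if (!is.null(.permCache[[key]])) return(.permCache[[key]])
  perm <- function(v) {
    if (length(v) == 1) return(matrix(v, 1, 1))
    out <- NULL
    for (i in seq_along(v))
      out <- rbind(out, cbind(v[i], perm(v[-i])))
    out
  }
  res <- perm(seq_len(p))
  .permCache[[key]] <- res
  res
}

## minimum over perfect matchings of the mean allele distance; a, b equal length
.bruvoMatch <- function(a, b) {
  p <- length(a)
  d <- .bruvoAllele(outer(a, b, "-"))
  P <- .permutations(p)
  m <- nrow(P)
  rowIdx <- matrix(rep(seq_len(p), each = m), m, p)
  lin <- as.vector(rowIdx + (P - 1L) * p)    # d[i, sigma(i)] linear indices
  vals <- matrix(d[lin], m, p)
  min(rowMeans(vals))
}

## genome-addition locus distance: pad the shorter allele multiset to the
## longer one with copies of its own alleles, minimising over pads and
## matchings.  a, b are integer repeat counts.
.bruvoLocus <- function(a, b) {
  if (length(a) > length(b)) { tmp <- a; a <- b; b <- tmp }
  gap <- length(b) - length(a)
  if (gap == 0) return(.bruvoMatch(a, b))
  pads <- as.matrix(expand.grid(rep(list(seq_along(a)), gap)))
  best <- Inf
  for (r in seq_len(nrow(pads))) {
    best <- min(best, .bruvoMatch(c(a, a[pads[r, ]]), b))
  }
  best
}

## convert allele sizes (bp) to integer repeat units
.sizesToRepeats <- function(sizes, repeatBp, offset = 0) {
  as.integer(round((sizes - offset) / repeatBp))
}

#' Bruvo distance between two multilocus genotypes
#'
#' Microsatellite distance under the stepwise mutation model: per allele pair
#' the distance is `1 - 2^(-|x|)` with `x` the repeat-unit difference; per
#' locus the distance is the minimum over perfect matchings of the mean
#' allele distance.  Genotypes of unequal ploidy (or with fewer scored
#' alleles) are handled by the genome-addition model: the shorter allele
#' multiset is padded with copies of its own alleles, minimising over pads.
#' The genotype distance is the mean over shared scored loci; with no shared
#' locus the distance is `NA` with a warning.
#'
#' @param g1,g2 named lists (locus -> numeric allele sizes in bp).
#' @param loci data.frame with columns `locus`, `repeat_bp`.
#' @param offsets optional named per-locus size offsets (defaults to the
#'   pairwise minimum allele size; only the repeat-unit differences matter).
#' @return numeric in \[0, 1\] (or `NA`).
#' @examples
#' loci <- data.frame(locus = "L1", repeat_bp = 1)
#' bruvoDistance(list(L1 = c(20, 23)), list(L1 = c(20, 24)), loci)  # 0.25
#' @export
bruvoDistance <- function(g1, g2, loci, offsets = NULL) {
  shared <- intersect(names(g1), names(g2))
  shared <- shared[!vapply(g1[shared], is.null, logical(1)) &
                   !vapply(g2[shared], is.null, logical(1))]
  if (!length(shared)) {
    warning("no shared scored loci; distance is NA")
    return(NA_real_)
  }
  per <- vapply(shared, function(l) {
    rb <- loci$repeat_bp[match(l, loci$locus)]
    off <- if (!is.null(offsets) && l %in% names(offsets)) offsets[[l]]
           else min(c(g1[[l]], g2[[l]]))
    a <- .sizesToRepeats(g1[[l]], rb, off)
    b <- .sizesToRepeats(g2[[l]], rb, off)
    .bruvoLocus(a, b)
  }, numeric(1))
  mean(per)
}

## per-locus pairwise distance matrices for a GenotypeTable
.bruvoPerLocus <- function(gt) {
  cvs <- names(gt@calls)
  n <- length(cvs)
  lociTab <- gt@loci
  out <- vector("list", nrow(lociTab))
  names(out) <- lociTab$locus
  for (li in seq_len(nrow(lociTab))) {
    l <- lociTab$locus[li]
    rb <- lociTab$repeat_bp[li]
    sizes <- lapply(gt@calls, function(g) g[[l]])
    off <- suppressWarnings(min(unlist(sizes)))
    reps <- lapply(sizes, function(s)
      if (is.null(s)) NULL else .sizesToRepeats(s, rb, off))
    D <- matrix(NA_real_, n, n, dimnames = list(cvs, cvs))
    diag(D) <- 0
    for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
      if (is.null(reps[[i]]) || is.null(reps[[j]])) next
      D[i, j] <- D[j, i] <- .bruvoLocus(reps[[i]], reps[[j]])
    }
    out[[li]] <- D
  }
  out
}

#' Pairwise Bruvo distance matrix for a genotype table
#'
#' @param gt a [GenotypeTable-class].
#' @return symmetric matrix in \[0, 1\] with zero diagonal; entries are means
#'   over the loci scored in both cultivars (`NA` when none are shared).
#' @export
bruvoDist <- function(gt) {
  perLocus <- .bruvoPerLocus(gt)
  arr <- simplify2array(perLocus)          # n x n x loci
  D <- apply(arr, c(1, 2), mean, na.rm = TRUE)
  D[is.nan(D)] <- NA_real_
  if (anyNA(D)) warning("cultivar pair(s) with no shared scored loci")
  D
}

#' Neighbour-joining tree from a distance matrix
#'
#' Standard NJ agglomeration; negative branch lengths are clamped to zero
#' with the deficit transferred to the sibling branch (path lengths through
#' the parent are preserved).  Two taxa yield a single split with the
#' distance shared equally.
#'
#' @param d symmetric distance matrix (complete, >= 2 taxa).
#' @return an `ape::phylo` tree.
#' @export
njTree <- function(d) {
  d <- as.matrix(d)
  if (anyNA(d)) stop("distance matrix must be complete")
  n <- nrow(d)
  if (n < 2) stop("at least 2 taxa are required")
  if (n == 2) {
    tr <- ape::read.tree(text = sprintf("(%s:%f,%s:%f);",
                                        rownames(d)[1], d[1, 2] / 2,
                                        rownames(d)[2], d[1, 2] / 2))
    return(tr)
  }
  tr <- ape::nj(stats::as.dist(d))
  ## clamp negative branches, moving the deficit to a sibling branch
  for (pass in 1:5) {
    neg <- which(tr$edge.length < 0)
    if (!length(neg)) break
    for (e in neg) {
      parent <- tr$edge[e, 1]
      sib <- setdiff(which(tr$edge[, 1] == parent), e)
      deficit <- tr$edge.length[e]
      tr$edge.length[e] <- 0
      if (length(sib)) {
        tr$edge.length[sib[1]] <- tr$edge.length[sib[1]] + deficit
      }
    }
  }
  tr$edge.length[tr$edge.length < 0] <- 0
  tr
}

#' Bootstrapped neighbour-joining tree from genotypes
#'
#' Loci are resampled with replacement; each replicate's Bruvo distance
#' matrix (mean of the resampled per-locus matrices) yields an NJ tree, and
#' the support of every internal bipartition of the full-data tree is the
#' fraction of replicate trees containing it.  Supports (percent) are stored
#' in the tree's node labels.  Deterministic given `seed`.
#'
#' @param gt a [GenotypeTable-class] with >= 2 loci.
#' @param nBoot bootstrap replicates (0 returns the tree without supports).
#' @param seed RNG seed.
#' @return an `ape::phylo`; with supports, node labels carry the percent
#'   support of each internal edge.
#' @export
bootstrapNJ <- function(gt, nBoot = 200, seed = 1) {
  if (nrow(gt@loci) < 2)
    stop("bootstrap requires at least 2 loci (nothing to resample)")
  perLocus <- .bruvoPerLocus(gt)
  arr <- simplify2array(perLocus)
  full <- apply(arr, c(1, 2), mean, na.rm = TRUE)
  if (anyNA(full) || any(is.nan(full)))
    stop("bootstrap requires a complete distance matrix")
  tree <- njTree(full)
  if (nBoot <= 0) return(tree)
  set.seed(seed)
  nl <- dim(arr)[3]
  reps <- vector("list", nBoot)
  for (b in seq_len(nBoot)) {
    pick <- sample.int(nl, nl, replace = TRUE)
    db <- apply(arr[, , pick, drop = FALSE], c(1, 2), mean, na.rm = TRUE)
    reps[[b]] <- njTree(db)
  }
  cnt <- ape::prop.clades(tree, reps, rooted = FALSE)
  cnt[is.na(cnt)] <- 0
  tree$node.label <- round(100 * cnt / nBoot, 1)
  tree
}

## within-individual allele-frequency encoding: one column per locus:allele,
## value = allele count / ploidy; missing loci imputed by the column mean
.encodeGenotypes <- function(gt) {
  cvs <- names(gt@calls)
  loci <- gt@loci$locus
  cols <- list()
  for (l in loci) {
    rb <- gt@loci$repeat_bp[match(l, gt@loci$locus)]
    all <- sort(unique(unlist(lapply(gt@calls, function(g) g[[l]]))))
    if (!length(all)) next
    block <- matrix(NA_real_, length(cvs), length(all),
                    dimnames = list(cvs, paste0(l, ".", all)))
    for (i in seq_along(cvs)) {
      s <- gt@calls[[i]][[l]]
      if (is.null(s)) next
      block[i, ] <- vapply(all, function(a) sum(s == a), numeric(1)) /
        gt@ploidy[[i]]
    }
    cols[[l]] <- block
  }
  X <- do.call(cbind, cols)
  for (j in seq_len(ncol(X))) {
    bad <- is.na(X[, j])
    if (any(bad)) X[bad, j] <- mean(X[, j], na.rm = TRUE)
  }
  X
}

## ridge-regularised linear discriminant fit on a score matrix
.ldaFit <- function(X, y, ridge = 1e-6) {
  y <- as.factor(y)
  classes <- levels(y)
  p <- ncol(X)
  mus <- do.call(rbind, lapply(classes, function(cl)
    colMeans(X[y == cl, , drop = FALSE])))
  rownames(mus) <- classes
  W <- matrix(0, p, p)
  for (cl in classes) {
    xc <- sweep(X[y == cl, , drop = FALSE], 2, mus[cl, ])
    W <- W + crossprod(xc)
  }
  W <- W / max(nrow(X) - length(classes), 1) + ridge * diag(p)
  priors <- as.numeric(table(y)[classes]) / length(y)
  Winv <- solve(W)
  ## discriminant axes: eigenvectors of W^-1 B (between-class scatter)
  grand <- colMeans(X)
  B <- matrix(0, p, p)
  for (k in seq_along(classes)) {
    dv <- mus[k, ] - grand
    B <- B + priors[k] * tcrossprod(dv)
  }
  ev <- eigen(Winv %*% B)
  nAxes <- min(length(classes) - 1, p)
  axes <- Re(ev$vectors[, seq_len(max(nAxes, 1)), drop = FALSE])
  list(classes = classes, means = mus, Winv = Winv, priors = priors,
       axes = axes, center = grand)
}

.ldaPredict <- function(fit, X) {
  ## gaussian discriminant with pooled covariance, log-scale for stability
  lp <- vapply(seq_along(fit$classes), function(k) {
    dv <- sweep(X, 2, fit$means[k, ])
    -0.5 * rowSums((dv %*% fit$Winv) * dv) + log(fit$priors[k])
  }, numeric(nrow(X)))
  lp <- matrix(lp, nrow = nrow(X))
  lp <- lp - apply(lp, 1, max)
  post <- exp(lp)
  post <- post / rowSums(post)
  colnames(post) <- fit$classes
  cls <- fit$classes[apply(post, 1, which.max)]
  list(class = cls, posterior = post)
}

#' Genetic clustering by discriminant analysis of principal components
#'
#' Genotypes are encoded as within-individual allele frequencies
#' (count/ploidy per allele column), transformed by PCA, and clustered by
#' K-means for K = 1..`kMax` (each with `nStarts` restarts, best run by
#' within-cluster sum of squares).  The number of clusters minimises
#' `BIC(K) = n ln(WSS_K / n) + K ln(n)`.  A ridge-regularised linear
#' discriminant analysis on the retained principal components then yields
#' discriminant axes and per-cultivar posterior memberships.
#'
#' All principal components are used at the K-means step; `nPC` components
#' (default: the smallest number explaining 90% of variance) are retained for
#' the discriminant step.
#'
#' @param gt a [GenotypeTable-class] with >= 2 cultivars.
#' @param kMax largest K tried (default 20; capped at n-1 with a warning).
#' @param nPC principal components retained for the discriminant step
#'   (`NULL` = 90% variance rule; see also [selectNPCs()]).
#' @param nStarts K-means restarts per K (default 200).
#' @param seed RNG seed (K-means initialisation).
#' @param ridge ridge term added to the pooled within-class covariance.
#' @return a [DAPCResult-class].
#' @export
dapc <- function(gt, kMax = 20, nPC = NULL, nStarts = 200, seed = 1,
                 ridge = 1e-6) {
  X <- .encodeGenotypes(gt)
  n <- nrow(X)
  if (n < 2) stop("at least 2 cultivars are required")
  if (kMax >= n) {
    warning("kMax capped at n - 1 = ", n - 1)
    kMax <- n - 1
  }
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  keep <- pc$sdev > 1e-10
  S <- pc$x[, keep, drop = FALSE]
  set.seed(seed)
  bic <- numeric(kMax)
  fits <- vector("list", kMax)
  totSS <- sum(sweep(S, 2, colMeans(S))^2)
  for (K in seq_len(kMax)) {
    if (K == 1) {
      wss <- totSS
      fits[[K]] <- list(cluster = rep(1L, n))
    } else {
      km <- stats::kmeans(S, centers = K, nstart = nStarts, iter.max = 100)
      wss <- km$tot.withinss
      fits[[K]] <- km
    }
    bic[K] <- n * log(wss / n) + K * log(n)
  }
  k <- which.min(bic)
  cluster <- fits[[k]]$cluster
  names(cluster) <- rownames(X)
  if (is.null(nPC)) {
    ve <- cumsum(pc$sdev[keep]^2) / sum(pc$sdev[keep]^2)
    nPC <- max(1L, which(ve >= 0.9)[1])
  }
  nPC <- min(nPC, ncol(S))
  if (k == 1) {
    post <- matrix(1, n, 1, dimnames = list(rownames(X), "1"))
    disc <- matrix(numeric(0), nrow = n, ncol = 0)
  } else {
    Sr <- S[, seq_len(nPC), drop = FALSE]
    fit <- .ldaFit(Sr, cluster, ridge = ridge)
    pred <- .ldaPredict(fit, Sr)
    post <- pred$posterior
    rownames(post) <- rownames(X)
    disc <- sweep(Sr, 2, fit$center) %*% fit$axes
    rownames(disc) <- rownames(X)
  }
  new("DAPCResult", bic = bic, k = as.integer(k), nPC = as.integer(nPC),
      assignments = as.integer(cluster) |> stats::setNames(rownames(X)),
      posterior = post, discriminant = disc)
}

#' Cross-validated choice of retained principal components
#'
#' For pre-assigned clusters, evaluates held-out assignment accuracy of the
#' discriminant step over candidate PC counts by stratified k-fold
#' cross-validation; returns the count maximising mean held-out accuracy,
#' ties resolved towards fewer components.
#'
#' @param gt a [GenotypeTable-class].
#' @param clusters named cluster assignment per cultivar (>= 2 clusters).
#' @param candidates candidate PC counts (default 1..min(20, n-2)).
#' @param folds number of CV folds (must not exceed n).
#' @param seed RNG seed for the fold split.
#' @param ridge ridge term of the discriminant fit.
#' @return list with `nPC` (selected count) and `accuracy` (named vector of
#'   mean held-out accuracy per candidate).
#' @export
selectNPCs <- function(gt, clusters, candidates = NULL, folds = 5, seed = 1,
                       ridge = 1e-6) {
  X <- .encodeGenotypes(gt)
  n <- nrow(X)
  if (folds > n) stop("folds (", folds, ") cannot exceed n (", n, ")")
  clusters <- clusters[rownames(X)]
  if (length(unique(clusters)) < 2)
    stop("at least 2 pre-assigned clusters are required")
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  keep <- pc$sdev > 1e-10
  S <- pc$x[, keep, drop = FALSE]
  if (is.null(candidates))
    candidates <- seq_len(min(20, ncol(S), n - 2))
  candidates <- candidates[candidates <= ncol(S)]
  set.seed(seed)
  ## stratified folds: spread each cluster across folds
  fold <- integer(n)
  for (cl in unique(clusters)) {
    idx <- sample(which(clusters == cl))
    fold[idx] <- rep_len(seq_len(folds), length(idx))
  }
  acc <- vapply(candidates, function(np) {
    hits <- 0L; tot <- 0L
    for (f in seq_len(folds)) {
      te <- which(fold == f); tr <- which(fold != f)
      if (!length(te) || length(unique(clusters[tr])) < 2) next
      fit <- .ldaFit(S[tr, seq_len(np), drop = FALSE], clusters[tr],
                     ridge = ridge)
      pred <- .ldaPredict(fit, S[te, seq_len(np), drop = FALSE])
      hits <- hits + sum(pred$class == as.character(clusters[te]))
      tot <- tot + length(te)
    }
    hits / max(tot, 1)
  }, numeric(1))
  names(acc) <- candidates
  best <- candidates[which(acc == max(acc))]
  list(nPC = min(best), accuracy = acc)
}
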