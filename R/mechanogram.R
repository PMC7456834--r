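#' @include AllClasses.R
NULL

## probe contact area for a 4 mm cylindrical flat head, mm^2
.PROBE_AREA_MM2 <- pi * 2^2

#' Extract the seven texture parameters from a mechanogram
#'
#' Computes, from a force-displacement compression curve: maximum force and
#' the strain at which it occurs, minimum force after the peak (skin rupture
#' valley) and its strain, final force at the end of the test, the trapezoidal
#' area under the curve, and the gradient (imitative Young's modulus) -- the
#' least-squares slope of the initial quasi-linear region, delimited by the
#' force trigger (default 0.02 N, the instrument's 2 g auto trigger) and a
#' configurable fraction (default 25%) of the maximum force.
#'
#' Ties for the maximum or minimum are broken by the first index.  The minimum
#' is searched strictly after the global maximum; a curve whose maximum is the
#' last sample is degenerate.
#'
#' @param curve a [MechCurve-class] (validated on entry).
#' @param gradientMode `"raw"` reports the gradient in N/% (slope of force vs
#'   percent strain); `"mpa"` converts to stress over fractional strain using
#'   the 4 mm probe contact area (12.566 mm^2), i.e. MPa.
#' @param forceTrigger lower force bound of the gradient window, N.
#' @param gradientFraction upper bound of the window as a fraction of the
#'   maximum force.
#' @return named numeric with elements `gradient`, `max_force`,
#'   `max_force_strain`, `min_force`, `min_force_strain`, `area`,
#'   `final_force`.
#' @examples
#' s <- seq(0, 90, by = 0.5)
#' f <- approx(c(0, 50, 70, 90), c(0, 5, 1, 2), xout = s)$y
#' cv <- new("MechCurve", strain = s, force = f, cultivar = "demo",
#'           timepoint = "harvest", fruit = "1", acquisitionRate = 500)
#' extractTextureProfile(cv)[["area"]]   # 215 N.%
#' @export
extractTextureProfile <- function(curve, gradientMode = c("raw", "mpa"),
                                  forceTrigger = 0.02,
                                  gradientFraction = 0.25) {
  gradientMode <- match.arg(gradientMode)
  ok <- validObject(curve, test = TRUE)
  if (!isTRUE(ok))
    stop("invalid mechanogram for fruit ", curve@cultivar, "/",
         curve@timepoint, "/", curve@fruit, ": ",
         paste(ok, collapse = "; "))
  s <- curve@strain; f <- curve@force
  iMax <- which.max(f)                       # first index on ties
  maxF <- f[iMax]
  if (maxF <= forceTrigger)
    stop("degenerate curve (no force peak above the trigger) for fruit ",
         curve@cultivar, "/", curve@timepoint, "/", curve@fruit)
  if (iMax == length(f))
    stop("degenerate curve (global maximum at the last sample) for fruit ",
         curve@cultivar, "/", curve@timepoint, "/", curve@fruit)
  post <- seq(iMax + 1L, length(f))
  iMin <- post[which.min(f[post])]           # first index on ties
  ## initial quasi-linear window: trigger level up to a fraction of the peak
  win <- which(f >= forceTrigger & f <= gradientFraction * maxF &
                 seq_along(f) <= iMax)
  if (length(win) < 2) {
    ## very coarse curves: fall back to everything up to the window ceiling
    win <- which(seq_along(f) <= iMax & f <= gradientFraction * maxF)
    if (length(win) < 2) win <- c(1L, iMax)
  }
  slope <- stats::cov(s[win], f[win]) / stats::var(s[win])
  if (gradientMode == "mpa")
    slope <- slope * 100 / .PROBE_AREA_MM2   # (N/mm^2) per unit strain
  area <- sum(diff(s) * (f[-1] + f[-length(f)]) / 2)
  c(gradient = slope,
    max_force = maxF, max_force_strain = s[iMax],
    min_force = f[iMin], min_force_strain = s[iMin],
    area = area, final_force = f[length(f)])
}

#' Extract texture profiles for a whole curve set
#'
#' @param curveSet a [MechCurveSet-class] or list of [MechCurve-class].
#' @param ... passed to [extractTextureProfile()].
#' @return data.frame with metadata columns (`cultivar`, `timepoint`,
#'   `fruit`) and the seven texture parameters, one row per curve.
#' @export
extractTextureProfiles <- function(curveSet, ...) {
  cl <- if (is(curveSet, "MechCurveSet")) curveSet@curves else curveSet
  rows <- lapply(cl, function(cv) {
    p <- extractTextureProfile(cv, ...)
    data.frame(cultivar = cv@cultivar, timepoint = cv@timepoint,
               fruit = cv@fruit, t(p))
  })
  do.call(rbind, rows)
}

#' Cultivar-level trait summary with storage indices
#'
#' Averages each texture parameter over fruit within cultivar and timepoint,
#' then reports the cohort minimum, maximum and mean of the cultivar means at
#' each timepoint, together with the storage index (log2 post/harvest ratio of
#' the cultivar means) summarised the same way.  Cultivars present at only one
#' timepoint contribute no storage index (a message reports how many).
#'
#' @param profiles data.frame as returned by [extractTextureProfiles()].
#' @param timepoints character(2), harvest then postharvest label.
#' @param floor positive floor substituted before the log-ratio.
#' @return list with `cultivarMeans` (cultivar x trait x timepoint long
#'   data.frame), `si` (cultivar x trait matrix of storage indices) and
#'   `summary` (per trait: min/max/mean at each timepoint and of the SI).
#' @export
summarizeTexture <- function(profiles,
                             timepoints = c("harvest", "postharvest"),
                             floor = 1e-3) {
  traits <- setdiff(colnames(profiles), c("cultivar", "timepoint", "fruit"))
  agg <- stats::aggregate(profiles[traits],
                          by = list(cultivar = profiles$cultivar,
                                    timepoint = profiles$timepoint),
                          FUN = mean)
  h <- agg[agg$timepoint == timepoints[1], , drop = FALSE]
  p <- agg[agg$timepoint == timepoints[2], , drop = FALSE]
  common <- intersect(h$cultivar, p$cultivar)
  lone <- setdiff(unique(agg$cultivar), common)
  if (length(lone))
    message(length(lone),
            " cultivar(s) present at a single timepoint; SI reported as missing: ",
            paste(lone, collapse = ", "))
  allCvs <- unique(agg$cultivar)
  si <- matrix(NA_real_, nrow = length(allCvs), ncol = length(traits),
               dimnames = list(allCvs, traits))
  if (length(common)) {
    hm <- as.matrix(h[match(common, h$cultivar), traits, drop = FALSE])
    pm <- as.matrix(p[match(common, p$cultivar), traits, drop = FALSE])
    si[common, ] <- storageIndex(hm, pm, floor = floor)
  }
  summ <- do.call(rbind, lapply(traits, function(tr) {
    data.frame(
      trait = tr,
      harvest_min = min(h[[tr]]), harvest_max = max(h[[tr]]),
      harvest_mean = mean(h[[tr]]),
      post_min = if (nrow(p)) min(p[[tr]]) else NA_real_,
      post_max = if (nrow(p)) max(p[[tr]]) else NA_real_,
      post_mean = if (nrow(p)) mean(p[[tr]]) else NA_real_,
      si_min = if (any(!is.na(si[, tr]))) min(si[, tr], na.rm = TRUE) else NA_real_,
      si_max = if (any(!is.na(si[, tr]))) max(si[, tr], na.rm = TRUE) else NA_real_,
      si_mean = if (any(!is.na(si[, tr]))) mean(si[, tr], na.rm = TRUE) else NA_real_)
  }))
  rownames(summ) <- NULL
  list(cultivarMeans = agg, si = si, summary = summ)
}
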