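#' @include AllClasses.R
NULL

.BIN_LABELS <- c("low", "middle-low", "middle-high", "high")

#' Quantile bins for one trait
#'
#' Assigns each cultivar to a quartile bin -- low (0-25%), middle-low
#' (25-50%), middle-high (50-75%), high (75-100%) -- with edges at the
#' 25/50/75th percentiles (linear-interpolation definition,
#' `quantile(type = 7)`).  Values equal to an edge fall in the lower bin;
#' missing values are labelled `"missing"`.  A constant vector is degenerate:
#' all values are labelled middle-low with a warning.
#'
#' @param values named numeric vector (>= 4 non-missing values).
#' @return list with `labels` (character, ordered factor levels
#'   low < middle-low < middle-high < high) and `edges` (the three percentile
#'   edges).
#' @examples
#' quantileBins(setNames(1:8, letters[1:8]))$labels
#' @export
quantileBins <- function(values) {
  ok <- !is.na(values)
  if (sum(ok) < 4)
    stop("quantile binning requires at least 4 non-missing values")
  edges <- stats::quantile(values[ok], probs = c(0.25, 0.5, 0.75),
                           type = 7, names = FALSE)
  labels <- rep(NA_character_, length(values))
  if (diff(range(values[ok])) == 0) {
    warning("constant trait values: degenerate single-bin output")
    labels[ok] <- "middle-low"
  } else {
    cutv <- cut(values[ok], breaks = c(-Inf, edges, Inf),
                labels = .BIN_LABELS, right = TRUE)
    labels[ok] <- as.character(cutv)
  }
  labels[!ok] <- "missing"
  names(labels) <- names(values)
  list(labels = labels, edges = edges)
}

#' Default roadmap trait subset
#'
#' The texture and volatile traits retained for the parental-selection table:
#' gradient, maximum force and maximum-force strain on the texture side;
#' methanol (m/z 33.033), acetaldehyde (45.031), ethanol (47.043), hexenal
#' isomers (99.08), C6 esters (117.092) and monoterpenes (137.134) on the
#' volatile side.
#'
#' @return character vector of trait names.
#' @export
defaultRoadmapTraits <- function() {
  c("gradient", "max_force", "max_force_strain",
    "mz_33.033", "mz_45.031", "mz_47.043",
    "mz_99.08", "mz_117.092", "mz_137.134")
}

#' Build the quantile roadmap table
#'
#' Bins every cultivar into quartile classes per trait, independently at
#' harvest and postharvest, producing the sortable parental-selection table.
#' Binning is rank-based, hence invariant to trait rescaling.
#'
#' @param harvest,post numeric matrices of cultivar means (cultivars x
#'   traits) sharing cultivars and trait columns.
#' @param traits optional trait subset; `NULL` or `character(0)` keeps all
#'   traits.  Unknown traits raise an error listing the known ones.
#' @return list with `table` (long data.frame: cultivar, trait, timepoint,
#'   bin) and `edges` (per trait x timepoint quantile edges).
#' @export
buildRoadmap <- function(harvest, post, traits = NULL) {
  common <- intersect(rownames(harvest), rownames(post))
  if (!length(common)) stop("matrices share no cultivars")
  harvest <- harvest[common, , drop = FALSE]
  post <- post[common, , drop = FALSE]
  if (!identical(colnames(harvest), colnames(post)))
    stop("harvest and post matrices must share trait columns")
  if (is.null(traits) || !length(traits)) {
    traits <- colnames(harvest)
  } else {
    unknown <- setdiff(traits, colnames(harvest))
    if (length(unknown))
      stop("unknown trait(s): ", paste(unknown, collapse = ", "),
           "; known traits: ", paste(colnames(harvest), collapse = ", "))
  }
  rows <- list(); edges <- list()
  for (tr in traits) {
    for (tp in c("harvest", "postharvest")) {
      v <- if (tp == "harvest") harvest[, tr] else post[, tr]
      names(v) <- common
      qb <- quantileBins(v)
      rows[[paste(tr, tp)]] <- data.frame(cultivar = common, trait = tr,
                                          timepoint = tp, bin = qb$labels,
                                          row.names = NULL)
      edges[[paste(tr, tp)]] <- qb$edges
    }
  }
  list(table = do.call(rbind, c(rows, list(make.row.names = FALSE))),
       edges = edges)
}
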