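#' @include AllClasses.R
NULL

#' Read and write the package's TSV dialects
#'
#' Curves travel as long-form TSV (`cultivar`, `timepoint`, `fruit`,
#' `strain_pct`, `force_N`); peak tables as samples-in-rows TSV with metadata
#' columns (`cultivar`, `timepoint`, `replicate`, `is_blank`) followed by one
#' column per m/z; genotypes as one row per cultivar x locus with
#' `allele_1..allele_6` and `ploidy`.
#'
#' @param x object to write.
#' @param path file path.
#' @name berryroad-io
NULL

#' @rdname berryroad-io
#' @param acquisitionRate points per second recorded in re-read curves.
#' @export
writeCurves <- function(x, path) {
  cl <- if (is(x, "MechCurveSet")) x@curves else x
  dt <- data.table::rbindlist(lapply(cl, function(cv)
    data.table::data.table(cultivar = cv@cultivar, timepoint = cv@timepoint,
                           fruit = cv@fruit, strain_pct = cv@strain,
                           force_N = cv@force)))
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}

#' @rdname berryroad-io
#' @export
readCurves <- function(path, acquisitionRate = 500) {
  dt <- data.table::fread(path, sep = "\t")
  sp <- split(dt, by = c("cultivar", "timepoint", "fruit"), sorted = TRUE)
  curves <- lapply(sp, function(d)
    new("MechCurve", strain = d$strain_pct, force = d$force_N,
        cultivar = d$cultivar[1], timepoint = d$timepoint[1],
        fruit = as.character(d$fruit[1]), acquisitionRate = acquisitionRate))
  new("MechCurveSet", curves = unname(curves))
}

#' @rdname berryroad-io
#' @export
writePeakTable <- function(x, path) {
  cd <- as.data.frame(colData(x))
  conc <- t(assay(x, "conc"))
  colnames(conc) <- vapply(mzValues(x), function(z) sprintf("%.10g", z),
                           character(1))
  out <- cbind(cd, as.data.frame(conc))
  data.table::fwrite(out, path, sep = "\t", row.names = FALSE)
  invisible(path)
}

#' @rdname berryroad-io
#' @export
readPeakTable <- function(path) {
  dt <- as.data.frame(data.table::fread(path, sep = "\t"))
  metaCols <- c("cultivar", "timepoint", "replicate", "is_blank")
  mzCols <- setdiff(colnames(dt), metaCols)
  conc <- t(as.matrix(dt[, mzCols, drop = FALSE]))
  meta <- dt[, metaCols]
  meta$cultivar <- as.character(meta$cultivar)
  meta$timepoint <- as.character(meta$timepoint)
  meta$cultivar[meta$cultivar == ""] <- NA_character_
  meta$timepoint[meta$timepoint == ""] <- NA_character_
  PeakTable(conc = conc, mz = as.numeric(mzCols), sampleData = meta)
}

#' @rdname berryroad-io
#' @export
writeGenotypes <- function(x, path) {
  rows <- list()
  for (cv in names(x@calls)) {
    for (l in names(x@calls[[cv]])) {
      al <- x@calls[[cv]][[l]]
      if (is.null(al)) next
      al6 <- c(al, rep(NA_real_, 6 - length(al)))
      rows[[paste(cv, l)]] <- data.frame(
        cultivar = cv, locus = l, ploidy = x@ploidy[[cv]],
        t(stats::setNames(al6, paste0("allele_", 1:6))))
    }
  }
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  data.table::fwrite(out, path, sep = "\t")
  invisible(path)
}

#' @rdname berryroad-io
#' @param loci locus table (`locus`, `repeat_bp`) for re-read genotypes.
#' @export
readGenotypes <- function(path, loci) {
  dt <- as.data.frame(data.table::fread(path, sep = "\t"))
  cvs <- unique(dt$cultivar)
  calls <- vector("list", length(cvs)); names(calls) <- cvs
  ploidy <- integer(length(cvs)); names(ploidy) <- cvs
  alleleCols <- paste0("allele_", 1:6)
  for (cv in cvs) {
    sub <- dt[dt$cultivar == cv, , drop = FALSE]
    g <- vector("list", nrow(sub)); names(g) <- sub$locus
    for (r in seq_len(nrow(sub))) {
      al <- as.numeric(sub[r, alleleCols])
      g[[r]] <- al[!is.na(al)]
    }
    calls[[cv]] <- g
    ploidy[[cv]] <- as.integer(sub$ploidy[1])
  }
  new("GenotypeTable", calls = calls, ploidy = ploidy, loci = loci)
}

#' @rdname berryroad-io
#' @export
writeTruth <- function(x, path) {
  jsonlite::write_json(
    lapply(x, function(el) {
      if (is.matrix(el)) as.data.frame(el) else el
    }),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null",
    force = TRUE)
  invisible(path)
}
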