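#' @include AllClasses.R
NULL

## cultivar x trait matrix for one timepoint from the long cultivar-means table
.textureMatrix <- function(cultivarMeans, timepoint) {
  sub <- cultivarMeans[cultivarMeans$timepoint == timepoint, , drop = FALSE]
  traits <- setdiff(colnames(sub), c("cultivar", "timepoint"))
  m <- as.matrix(sub[, traits, drop = FALSE])
  rownames(m) <- sub$cultivar
  m
}

.writeMatrix <- function(m, path) {
  out <- data.frame(cultivar = rownames(m), as.data.frame(m),
                    check.names = FALSE)
  data.table::fwrite(out, path, sep = "\t")
  invisible(path)
}

## one multivariate view: prepare matrix, PCA, Ward clustering, outputs
.clusterView <- function(m, type, kMax, outDir, tag) {
  tm <- buildTraitMatrix(m, type = type)
  pca <- pcaTraits(tm, scale = FALSE)       # tm already standardized
  cl <- wardCluster(tm, k = NULL, kMax = kMax)
  scores <- data.frame(cultivar = rownames(tm),
                       pca@scores[, seq_len(min(5, ncol(pca@scores))),
                                  drop = FALSE],
                       cluster = cl@labels)
  data.table::fwrite(scores, file.path(outDir, paste0(tag, "_scores.tsv")),
                     sep = "\t")
  phylo <- ape::as.phylo(cl@hclust)
  ape::write.tree(phylo, file.path(outDir, paste0(tag, "_dendrogram.nwk")))
  list(pca = pca, cluster = cl)
}

#' Run the whole phenotyping pipeline on a synthetic cohort
#'
#' Chains every stage -- cohort simulation, mechanogram feature extraction,
#' peak-table reduction, storage indices, PCA + Ward clustering of the
#' harvest / postharvest / SI views, genetic structure (Bruvo distance,
#' bootstrapped NJ tree, DAPC), phenotype-vs-genotype association, and the
#' quantile roadmap -- and writes every table, tree and a run manifest (seed,
#' package version, md5 file hashes) into `outDir`.  Fully reproducible for a
#' fixed seed.
#'
#' @param config a [CohortConfig-class]; `config@seed` is overridden by
#'   `seed` when given.
#' @param outDir output directory (created if needed).
#' @param seed optional integer overriding `config@seed`.
#' @param nBoot NJ bootstrap replicates (desk-scale default 200).
#' @param kMax cluster-count search ceiling for the phenotype views.
#' @param dapcKMax largest K tried by DAPC.
#' @param dapcStarts K-means restarts per K.
#' @return (invisibly) list with the cohort, intermediate results and the
#'   manifest.
#' @examples
#' \donttest{
#' res <- runPipeline(cohortConfig(nCultivars = 8, nFruit = 2, seed = 3),
#'                    outDir = tempfile("run"))
#' res$manifest$n_files
#' }
#' @export
runPipeline <- function(config = cohortConfig(), outDir, seed = NULL,
                        nBoot = 200, kMax = 10, dapcKMax = 20,
                        dapcStarts = 200) {
  if (!is.null(seed)) config@seed <- as.integer(seed)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  keep <- function(p) { paths <<- c(paths, p); p }

  cohort <- simulateCohort(config)
  writeCurves(cohort@curves, keep(file.path(outDir, "curves.tsv")))
  writePeakTable(cohort@peaks, keep(file.path(outDir, "peaks_raw.tsv")))
  writeGenotypes(cohort@genotypes, keep(file.path(outDir, "genotypes.tsv")))
  writeTruth(cohort@truth[c("textureArchetype", "vocArchetype",
                            "population", "seed")],
             keep(file.path(outDir, "truth.json")))

  ## texture: per-fruit profiles, cultivar means, SI, Table-2-style summary
  profiles <- extractTextureProfiles(cohort@curves)
  data.table::fwrite(profiles, keep(file.path(outDir, "texture_profiles.tsv")),
                     sep = "\t")
  texsum <- summarizeTexture(profiles, timepoints = config@timepoints)
  data.table::fwrite(texsum$summary,
                     keep(file.path(outDir, "texture_summary.tsv")),
                     sep = "\t")
  .writeMatrix(texsum$si, keep(file.path(outDir, "si_texture.tsv")))

  ## volatiles: filter, reduce, SI
  red <- reducePeaks(cohort@peaks, floor = config@concFloor)
  writePeakTable(red$table, keep(file.path(outDir, "peaks_reduced.tsv")))
  jsonlite::write_json(red$report,
                       keep(file.path(outDir, "peak_filter_report.json")),
                       dataframe = "rows", na = "null", digits = NA,
                       auto_unbox = TRUE, pretty = TRUE)
  vocH <- cultivarMeanMatrix(red$table, config@timepoints[1])
  vocP <- cultivarMeanMatrix(red$table, config@timepoints[2])
  vocSI <- siMatrix(vocH, vocP, floor = config@concFloor)
  .writeMatrix(vocSI, keep(file.path(outDir, "si_voc.tsv")))
  ann <- annotatePeaks(mzValues(red$table))
  data.table::fwrite(ann, keep(file.path(outDir, "peak_annotation.tsv")),
                     sep = "\t")

  ## multivariate views: harvest / postharvest / SI for texture and volatiles
  texH <- .textureMatrix(texsum$cultivarMeans, config@timepoints[1])
  texP <- .textureMatrix(texsum$cultivarMeans, config@timepoints[2])
  views <- list(
    texture_harvest = list(m = texH, type = "texture"),
    texture_postharvest = list(m = texP, type = "texture"),
    texture_si = list(m = texsum$si, type = "texture"),
    voc_harvest = list(m = vocH, type = "voc"),
    voc_postharvest = list(m = vocP, type = "voc"),
    voc_si = list(m = vocSI, type = "texture")  # SI already on log2 scale
  )
  multiv <- lapply(names(views), function(tag) {
    v <- views[[tag]]
    .clusterView(v$m, v$type, kMax, outDir, tag)
  })
  names(multiv) <- names(views)
  for (tag in names(views))
    paths <- c(paths, file.path(outDir, paste0(tag, "_scores.tsv")),
               file.path(outDir, paste0(tag, "_dendrogram.nwk")))

  ## genetic structure
  D <- bruvoDist(cohort@genotypes)
  .writeMatrix(D, keep(file.path(outDir, "bruvo_distance.tsv")))
  tree <- bootstrapNJ(cohort@genotypes, nBoot = nBoot,
                      seed = config@seed + 1L)
  ape::write.tree(tree, keep(file.path(outDir, "nj_tree.nwk")))
  dap <- dapc(cohort@genotypes, kMax = dapcKMax, nStarts = dapcStarts,
              seed = config@seed + 2L)
  data.table::fwrite(
    data.frame(cultivar = names(dap@assignments),
               cluster = dap@assignments, dap@posterior,
               check.names = FALSE),
    keep(file.path(outDir, "dapc_assignments.tsv")), sep = "\t")
  data.table::fwrite(data.frame(K = seq_along(dap@bic), BIC = dap@bic),
                     keep(file.path(outDir, "dapc_bic.tsv")), sep = "\t")

  ## phenotype vs genotype association
  assoc <- list()
  for (tag in c("texture_harvest", "voc_harvest")) {
    lab <- clusterLabels(multiv[[tag]]$cluster)
    gen <- clusterLabels(dap)
    a <- clusterAssociation(lab, gen, nPerm = 999, seed = config@seed + 3L)
    assoc[[tag]] <- list(ari = a$ari, p = a$p)
  }
  jsonlite::write_json(assoc, keep(file.path(outDir, "association.json")),
                       auto_unbox = TRUE, digits = NA)

  ## parental-selection roadmap over combined texture + volatile traits
  common <- intersect(rownames(texH), rownames(vocH))
  harvestAll <- cbind(texH[common, , drop = FALSE],
                      vocH[common, , drop = FALSE])
  postAll <- cbind(texP[common, , drop = FALSE], vocP[common, , drop = FALSE])
  traits <- intersect(defaultRoadmapTraits(), colnames(harvestAll))
  if (!length(traits)) traits <- NULL
  roadmap <- buildRoadmap(harvestAll, postAll, traits = traits)
  data.table::fwrite(roadmap$table, keep(file.path(outDir, "roadmap.tsv")),
                     sep = "\t")

  manifest <- list(
    seed = config@seed,
    package_version = as.character(utils::packageVersion("berryroad")),
    n_cultivars = config@nCultivars,
    n_files = length(paths),
    files = lapply(stats::setNames(paths, basename(paths)), function(p)
      unname(tools::md5sum(p)))
  )
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(cohort = cohort, profiles = profiles, textureSummary = texsum,
                 reduced = red, vocSI = vocSI, multivariate = multiv,
                 bruvo = D, njTree = tree, dapc = dap, association = assoc,
                 roadmap = roadmap, manifest = manifest))
}
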