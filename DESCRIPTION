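Package: berryroad
Title: Harvest-to-Postharvest Phenotyping Roadmap for Blueberry Quality and Storability
Version: 0.9.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for phenotyping fruit quality and storability across a germplasm
    collection assessed at harvest and after cold storage. Extracts the seven standard
    texture parameters from force-displacement compression curves (mechanograms),
    reduces direct-injection PTR-ToF-MS volatile peak tables by blank-based noise and
    isotope-correlation filters, computes log2 storage indices, clusters cultivars by
    PCA and Ward hierarchical clustering with data-driven cluster-count selection,
    analyses mixed-ploidy SSR genotypes (tail-corrected allele sizes, Bruvo distance,
    bootstrapped neighbour-joining trees, DAPC-style clustering with BIC model
    selection), and assembles quantile-binned parental-selection tables. Ships a
    synthetic cohort generator with known ground truth so every stage of the pipeline
    is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment,
    ape,
    mclust,
    igraph,
    jsonlite,
    data.table
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'cohort-sim.R'
    'genetics.R'
    'io.R'
    'mechanogram.R'
    'multivariate.R'
    'pipeline.R'
    'roadmap.R'
    'storage-index.R'
    'voc-peaks.R'
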