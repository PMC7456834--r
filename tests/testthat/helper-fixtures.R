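# shared fixtures: all synthetic, generated in code at test time

# sample a piecewise-linear curve through the given nodes on a uniform grid
# (node strains inserted so the polyline is exact)
makeCurve <- function(nodesS, nodesF, step = 0.5, cultivar = "T",
                      timepoint = "harvest", fruit = "1") {
  grid <- sort(unique(c(seq(min(nodesS), max(nodesS), by = step), nodesS)))
  force <- approx(nodesS, nodesF, xout = grid)$y
  new("MechCurve", strain = grid, force = force, cultivar = cultivar,
      timepoint = timepoint, fruit = fruit, acquisitionRate = 500)
}

# small cohort for fast end-to-end style tests
smallConfig <- function(seed = 1, ...) {
  cohortConfig(nCultivars = 6, nFruit = 2, nVocReplicates = 2, nBlanks = 4,
               strainStep = 0.5, seed = seed, ...)
}

# four planted texture archetypes distinguished along near-orthogonal trait
# axes (slope, breaking force, deformation strains, terminal force) so the
# standardized centroids are roughly equidistant; with the tight spreads of
# fourArchetypeConfig() the centroid separation exceeds 6x the within-
# archetype SD, which the recovery tests verify explicitly
fourArchetypes <- function() {
  data.frame(
    name = c("turgid", "firm", "gummy", "crisp"),
    gradient         = c(2.30, 1.50, 1.10, 1.50),
    max_force        = c(3.60, 5.00, 3.60, 4.20),
    max_force_strain = c(3.80, 3.80, 4.90, 3.40),
    min_force        = c(0.80, 1.10, 0.80, 0.80),
    min_force_strain = c(5.60, 5.60, 6.80, 5.30),
    final_force      = c(1.50, 1.50, 1.30, 2.10),
    shift_gradient         = -0.95,
    shift_max_force        =  0.07,
    shift_max_force_strain =  0.31,
    shift_min_force        =  0.21,
    shift_min_force_strain =  0.24,
    shift_final_force      =  0.14,
    stringsAsFactors = FALSE
  )
}

fourArchetypeConfig <- function(seed, nCultivars = 24, nFruit = 8) {
  cohortConfig(nCultivars = nCultivars, nFruit = nFruit,
               textureArchetypes = fourArchetypes(),
               archetypeProbs = rep(1, 4),
               cultivarCV = 0.01, fruitCV = 0.01, forceNoiseSd = 0.003,
               textureShiftSd = 0.1, strainStep = 0.1, seed = seed)
}

# strongly diverged populations for genetic-recovery simulations
divergentGenotypes <- function(seed, nCultivars = 45, nPopulations = 3,
                               hexaploidPops = integer(0)) {
  set.seed(seed)
  simulateGenotypes(sprintf("G%02d", seq_len(nCultivars)),
                    nPopulations = nPopulations,
                    hexaploidPops = hexaploidPops,
                    popProbs = rep(1, nPopulations),
                    popDivergence = 8, mutationGeomProb = 0.35)
}

# random genotype at the given loci for oracle comparisons
randomGenotype <- function(loci, ploidy, nAlleles = ploidy) {
  g <- lapply(seq_len(nrow(loci)), function(l)
    100 + loci$repeat_bp[l] * sample(10:40, nAlleles, replace = TRUE))
  names(g) <- loci$locus
  g
}
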