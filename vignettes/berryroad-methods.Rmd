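---
title: "Methods: phenotyping fruit quality and storability with berryroad"
author: "berryroad authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: phenotyping fruit quality and storability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(berryroad)
```

# Scope and model

`berryroad` implements a harvest-to-postharvest phenotyping workflow for a
berry germplasm collection: instrument-level inputs (force--displacement
compression curves, direct-injection PTR-ToF-MS peak tables, SSR genotypes
with mixed ploidy) are turned into per-cultivar quality traits, storage
indices, multivariate cultivar groupings, a genetic-structure view, and
quantile-binned parental-selection tables. Because no raw per-fruit data are
publicly deposited for this kind of study, the package is built around a
synthetic cohort generator with known ground truth: every downstream stage
is validated by parameter recovery on cohorts whose texture archetypes,
volatile trajectories and population structure are planted.

# Mechanograms and the seven texture parameters

A mechanogram records force (N) against percent deformation (strain) while a
4 mm cylindrical probe compresses a berry to 90% deformation at
100 mm min^-1^, sampled at 500 points per second. Seven parameters summarise
the curve: maximum force and its strain, the post-peak minimum force (skin
rupture valley) and its strain, the final force at 90% deformation, the
trapezoidal area under the curve, and the *gradient* (imitative Young's
modulus) -- the slope of the initial quasi-linear region.

Two conventions needed fixing where standard practice leaves latitude:

* **Gradient window.** The initial region is delimited by the instrument's
  auto force trigger (0.02 N, i.e. 2 g) below and a configurable fraction of
  the maximum force (default 25%) above; the gradient is the least-squares
  slope over that window. This is the usual convention for an initial
  quasi-linear fit; the window fraction is a parameter
  (`gradientFraction`).
* **Units.** The gradient is reported natively in N/% (force slope per
  percent strain, `gradientMode = "raw"`); a stress mode
  (`gradientMode = "mpa"`) divides force by the probe contact area
  (4 mm diameter, 12.566 mm^2^) and uses fractional strain, giving MPa.
  Published tables quote both conventions with numerically similar ranges,
  so both are exposed.

Ties at the maximum or minimum resolve to the first index; the minimum is
searched strictly after the global maximum, and a curve whose maximum is its
last sample is rejected as degenerate (no post-peak segment exists).

## The synthetic curve family

Simulated curves are piecewise linear through five nodes: origin; a knee at
40% of the peak force reached with slope equal to the planted gradient; the
force peak; the rupture valley; and the terminal force at 90% strain. The
extra knee node matters: with a single ramp from origin to peak, the initial
slope would be tied to `max_force / max_force_strain`, and the planted
storage shift of the gradient (about -0.95 log2 units in cohort averages)
could not be varied independently of the force and strain shifts (+0.07 and
+0.31). A free initial-slope segment decouples them while keeping closed-form
ground truth for all seven parameters.

Node strains are inserted into the uniform acquisition grid, so the sampled
polyline passes through the segment endpoints exactly. With zero force noise
the extractor therefore recovers the planted parameters to machine precision
(the trapezoid rule is exact on linear pieces); this is asserted over 1,000
simulated fruit. With Gaussian force noise at 1% of the peak force, the
median recovery error is below 2% for the maximum force and below 5% for the
gradient.

Two extracted quantities are intrinsically noise-limited, which matters when
designing recovery experiments: the gradient window spans only a few tenths
of a percent strain for stiff fruit (so coarse strain grids leave too few
points in the window), and the valley strain is ill-conditioned because the
terminal segment rises very gently (a small force noise moves the argmin by
a percent or more of strain). Recovery fixtures therefore sample at 0.1%
strain steps and average several fruit per cultivar.

Parameters out of range (e.g. a valley above the terminal force) are clipped
to a valid curve with a warning, and the recorded ground truth reflects the
clipped values.

# Volatile peak tables and the two reduction filters

The PTR-ToF-MS data model is a samples x m/z concentration matrix (ug/kg)
with blank headspace samples flagged. Reduction applies two filters in a
fixed order:

1. **Noise filter.** Per mass peak, a one-sided Welch test (unequal
   variances) of fruit samples against blanks on log-transformed
   concentrations; peaks with p >= alpha (default 0.05) are treated as
   blank-level noise. The test is pooled over timepoints; no multiplicity
   correction is applied by default, matching common practice for this
   pre-filter (a `p.adjust` toggle exists). The log transform is the right
   scale because replicate spread is multiplicative.
2. **Correlation filter.** A graph is built on the surviving peaks with
   edges where the product-moment correlation of log concentrations strictly
   exceeds 0.99; each connected component keeps one representative -- the
   lowest m/z, because monoisotopic parents are lighter than their
   isotopologues -- with ties broken by higher mean concentration. Constant
   peaks have undefined correlation and are treated as uncorrelated.

Correlations are computed over fruit samples. Blank channels are
floor-censored at the trace reporting level (10^-3^ ug/kg), which would break
the exact proportionality of isotope channels in blank columns and only blur
the estimate; the filter's purpose (isotopologue contraction) concerns fruit
signal. On synthetic cohorts, planted exact-multiple isotopes are removed
with probability 1 in noise-free mode and >= 99% under 5% multiplicative
noise at >= 50 samples, while blank-equivalent peaks are retained at the
type-I rate alpha.

Retained peaks are annotated against a packaged m/z library of tentative
identities (nearest match within +-0.005).

# Storage index

For any positive trait value measured at harvest (Q~H~) and after storage
(Q~PH~), the storage index is SI = log~2~(Q~PH~/Q~H~); positive values mean
the trait was enhanced during storage. Values below a floor (default
10^-3^) are replaced by the floor first, so trace-level zeros yield finite
indices. SI is computed on cultivar means over replicates, then summarised
(min/max/mean) across cultivars; the mean of per-cultivar SIs deliberately
differs from the SI of cohort means (Jensen gap), and both conventions are
covered by tests.

# Multivariate views

Trait matrices (harvest, postharvest, SI; texture or volatile) are prepared
by: log10 transform for volatile concentrations (they span about five orders
of magnitude), median imputation of missing cells, and column
standardization (traits mix N, %, N/% and ug/kg). PCA is centred (and scaled
in standardized mode) with component signs fixed by making the
largest-magnitude loading positive. Clustering is agglomerative with the
Ward criterion on Euclidean distances (`ward.D2`).

The number of clusters is selected by an inertia-jump rule: with W(k) the
within-cluster inertia of the k-cluster cut, choose the K maximising
(W(K-1) - W(K)) / (W(K) - W(K+1)) over 2..kMax (default 10) -- the elbow
where one further split stops paying. When the profile is flat (maximum
jump below 3) the documented default K = 2 is returned with a
low-confidence flag. The rule is a stand-in for an unspecified
"statistically significant clusters" criterion and is validated by
recovering four planted archetypes (centroid separation >= 6 sigma) with
ARI >= 0.9 in >= 95% of seeded cohorts. A caveat learned from those
simulations: the rule compares successive inertia ratios, so it prefers
cluster geometries whose centroids are roughly equidistant; with strongly
elongated centroid configurations intermediate jumps can compete with the
signal-to-noise jump, and the selection drifts to coarser cuts.

Phenotype-genotype agreement is quantified by the adjusted Rand index with a
permutation p-value, p = (1 + #{permuted ARI >= observed}) / (nPerm + 1).

# Genetic structure

**Allele sizes** from capillary electrophoresis are corrected by the length
of the universal primer tail (T7: 20 nt; M13, M13R, D12S1090f: 18 nt) and
converted to repeat units by nearest integer of (size - offset) / repeat
length, with the cohort-minimum allele as default offset (only repeat-unit
differences enter the distance).

**Bruvo distance.** Per allele pair the stepwise-mutation distance is
1 - 2^-|x|^ with x the repeat-unit difference; per locus the minimum over
perfect matchings of the mean allele distance; per genotype the mean over
shared loci. Mixed ploidy uses the genome-addition model: the smaller allele
multiset is padded with copies of its own alleles, minimising over pads --
the simplest well-defined variant, also applied to partially scored loci.
The implementation enumerates matchings via precomputed permutation tables;
an independent recursive oracle checks exact agreement on 200 random
mixed-ploidy pairs.

**Trees.** Neighbour-joining on the Bruvo matrix, with negative branch
lengths clamped to zero and the deficit moved to a sibling branch. Bootstrap
supports resample loci with replacement (per-locus distance matrices are
precomputed, so replicates are cheap); support is the fraction of replicate
trees containing each bipartition. The desk-scale default is 200 replicates
(1,000 remains standard at publication scale and is a parameter).

**DAPC.** Genotypes are encoded as within-individual allele frequencies
(count/ploidy per allele column), rotated by PCA, and clustered by K-means
for K = 1..20 with 200 restarts each; the number of clusters minimises
BIC(K) = n ln(WSS~K~/n) + K ln(n). All principal components enter the
K-means step; the discriminant step retains the smallest set of components
explaining 90% of variance (or a cross-validated count via `selectNPCs`,
ties resolved to fewer components) and uses a ridge-regularised
(10^-6^) linear discriminant with pooled within-class covariance to produce
axes and posterior memberships.

A note on BIC consistency at this cohort scale (n around 45, 6 loci): the
argmin-BIC rule is reliable when within-population allele diversity is
realistic for microsatellite panels (expected heterozygosity near 0.8, i.e.
a signed-geometric repeat spread with success probability about 0.35). With
markedly under-dispersed alleles the best K-means split of even a panmictic
sample removes slightly more inertia than the ln(n) penalty, and BIC
overshoots by one cluster. The population-recovery simulations therefore
use the heterozygosity-realistic spread; this is a property of the BIC
criterion at small n, not of the implementation.

# Quantile roadmap

Each trait is binned per timepoint at the 25/50/75th percentiles
(linear-interpolation definition) into low, middle-low, middle-high and high
classes; edge values fall in the lower bin, missing values are labelled, and
constant traits degenerate to a single bin with a warning. Binning is
rank-based and hence invariant to trait rescaling. The default trait subset
mirrors the traits a breeder would shortlist (gradient, maximum force and
its strain; methanol, acetaldehyde, ethanol, hexenal isomers, C6 esters and
monoterpene mass peaks); the exact published shortlist sits in unavailable
supplementary material, so this default is a documented stand-in.

# The synthetic cohort

Defaults emulate the targeted study design: 46 cultivars x 2 timepoints
(harvest, 6 weeks of cold storage), 20 fruit per cultivar for texture, 3
headspace replicates plus 6 blanks for volatiles, and 4 planted genetic
populations (one hexaploid, matching the rabbiteye/highbush split) at 6 SSR
loci.

* **Texture**: three archetypes (turgid / firm / gummy) with lognormal
  between-cultivar (10%) and fruit-level (5%) spread; storage shifts planted
  at the published cohort-average storage indices (gradient -0.95, max-force
  strain +0.31, etc.) with 0.3 log2 units of per-cultivar spread.
* **Volatiles**: class means and log2 storage shifts follow the published
  cohort table (ethanol +6.68, acetaldehyde +3.21, esters up, terpenes and
  C6 aldehydes down); concentrations are lognormal (between-cultivar sd of
  log 0.6, replicate CV 15%), a small fermentative archetype (11% of
  cultivars) amplifies fermentation-class shifts 1.5x and a stable group
  (25%) damps them to 0.6x; values below 10^-3^ ug/kg are reported at the
  floor. Nuisance channels: blank-distributed noise peaks and isotope
  channels that are exact scalar multiples (factor 0.01--0.2) of abundant
  parents.
* **Genetics**: population modal alleles sit on an equally spaced grid
  (default 6 repeat units apart, +-1 jitter); individual alleles add a
  signed geometric offset (default success probability 0.5). Hexaploids are
  six draws, tetraploids four.

What the generator does *not* emulate: field and season effects, real
between-trait correlation structure beyond what the archetypes induce,
pedigree relatedness within populations, chromatographic artefacts, or raw
time-of-flight spectra. Passing recovery tests therefore demonstrates
correctness of the algorithms under the stated statistical model, not
instrument-level validity on real data.

# Problem sizes and numerical choices

Simulation scales used by the test and acceptance suites are desk-scale
choices made by the package: 1,000 fruit for extraction recovery; 10^4^
randomized cases for the SI identities; 1,000 null peaks for the filter
calibration; 200 genotype pairs for the Bruvo oracle; 50 seeded cohorts for
each clustering/population recovery rate; 20 single-population runs for the
BIC consistency check; NJ bootstrap at 200 replicates; the
population-recovery simulations run K-means with 50 restarts over K up to 10
(the pipeline itself keeps the 200-restart, K up to 20 defaults). The full default
cohort pipeline (`runPipeline`) runs in well under ten minutes on one CPU
and is byte-for-byte reproducible for a fixed seed (file hashes are recorded
in a manifest).

Numerical conventions collected in one place: force trigger 0.02 N;
gradient window ceiling 0.25 x max force; concentration floor 10^-3^ ug/kg;
correlation threshold strictly > 0.99; Welch test on log(conc + floor);
quantile type 7; K-means best-of-restarts by WSS with first-occurrence tie
break; LDA ridge 10^-6^; cluster-count flatness threshold 3; all RNG derived
from a single integer seed per run.
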