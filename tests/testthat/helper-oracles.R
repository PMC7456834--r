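# independent brute-force oracles, kept free of the package's implementation

# all perfect matchings of equal-length repeat vectors, by plain recursion
.oracleMatch <- function(a, b) {
  if (length(a) == 1) return(1 - 2^(-abs(a - b)))
  best <- Inf
  for (j in seq_along(b)) {
    d1 <- 1 - 2^(-abs(a[1] - b[j]))
    rest <- .oracleMatch(a[-1], b[-j])
    # rest is the minimal MEAN over the remaining alleles
    tot <- (d1 + rest * (length(a) - 1)) / length(a)
    best <- min(best, tot)
  }
  best
}

# all pads (combinations with repetition of the shorter vector's own alleles)
.oraclePads <- function(v, gap) {
  if (gap == 0) return(list(integer(0)))
  out <- list()
  rec <- function(prefix, startIdx) {
    if (length(prefix) == gap) { out[[length(out) + 1]] <<- prefix; return() }
    for (i in startIdx:length(v)) rec(c(prefix, v[i]), i)
  }
  rec(integer(0), 1)
  out
}

# genome-addition Bruvo distance at one locus, exhaustive
bruvoOracleLocus <- function(a, b) {
  if (length(a) > length(b)) { tmp <- a; a <- b; b <- tmp }
  gap <- length(b) - length(a)
  best <- Inf
  for (pad in .oraclePads(a, gap))
    best <- min(best, .oracleMatch(c(a, pad), b))
  best
}

# whole-genotype oracle on allele sizes (bp), mirroring the documented
# size -> repeat-unit conversion (pairwise-minimum offset)
bruvoOracle <- function(g1, g2, loci) {
  shared <- intersect(names(g1), names(g2))
  per <- sapply(shared, function(l) {
    rb <- loci$repeat_bp[match(l, loci$locus)]
    off <- min(c(g1[[l]], g2[[l]]))
    a <- round((g1[[l]] - off) / rb)
    b <- round((g2[[l]] - off) / rb)
    bruvoOracleLocus(a, b)
  })
  mean(per)
}

# closed-form trapezoid area of a piecewise-linear curve given its nodes
polylineArea <- function(nodesS, nodesF) {
  sum(diff(nodesS) * (head(nodesF, -1) + tail(nodesF, -1)) / 2)
}
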