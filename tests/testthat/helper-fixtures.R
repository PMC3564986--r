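# Shared fixtures, all generated in code.

tinyMap <- function(pos = c(0, 25, 50, 75, 100), chrom = rep("1", length(pos)),
                    marker = sprintf("m%02d", seq_along(pos))) {
  new("GeneticMap", marker = marker, chrom = chrom, pos = pos)
}

# small NAM-like panel with matching map
smallPanel <- function(nPop = 2, linesPerPop = 60, nChrom = 2,
                       totalLength = 120, nMarkers = 24, seed = 1) {
  map <- simulateMap(nChrom, totalLength, nMarkers, seed = seed)
  simulateNAMPanel(map, nPop = nPop, linesPerPop = linesPerPop,
                   seed = seed + 1)
}

# restricted log-likelihood of the univariate animal model, dense and
# independent of the package's internals (oracle)
denseRemlLogLik <- function(y, X, A, sg2, se2) {
  V <- sg2 * A + se2 * diag(length(y))
  Vi <- solve(V)
  b <- solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% y)
  r <- y - X %*% b
  -0.5 * (determinant(V)$modulus[1] + drop(t(r) %*% Vi %*% r) +
          determinant(t(X) %*% Vi %*% X)$modulus[1] +
          (length(y) - ncol(X)) * log(2 * pi))
}
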