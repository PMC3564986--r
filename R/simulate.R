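#' Simulate a NAM-like genetic map
#'
#' Builds a genetic map with \code{nChrom} chromosomes of equal length whose
#' first and last markers are pinned at the chromosome ends and whose interior
#' markers are placed uniformly at random. Defaults mirror a typical maize NAM
#' marker panel: about 820 markers covering roughly 1,390 cM on 10
#' chromosomes.
#'
#' @param nChrom number of chromosomes (>= 1).
#' @param totalLength total map length in cM, split equally across
#'   chromosomes.
#' @param nMarkers total marker count; at least \code{2 * nChrom} so both ends
#'   of every chromosome can be pinned.
#' @param seed integer seed; equal seeds give identical maps.
#' @return a \linkS4class{GeneticMap}.
#' @examples
#' simulateMap(nChrom = 2, totalLength = 200, nMarkers = 20, seed = 1)
#' @export
simulateMap <- function(nChrom = 10, totalLength = 1389, nMarkers = 819,
                        seed = 1) {
  stopifnot(nChrom >= 1, totalLength > 0)
  if (nMarkers < 2 * nChrom)
    stop("nMarkers must be at least 2 * nChrom to pin both chromosome ends")
  chrLen <- totalLength / nChrom
  # distribute markers as evenly as possible, two reserved per chromosome
  base <- rep(nMarkers %/% nChrom, nChrom)
  extra <- nMarkers %% nChrom
  if (extra > 0) base[seq_len(extra)] <- base[seq_len(extra)] + 1
  withSeed(seed, {
    chrom <- character(0); pos <- numeric(0)
    for (cc in seq_len(nChrom)) {
      k <- base[cc]
      inner <- sort(runif(k - 2, min = 0, max = chrLen))
      p <- c(0, inner, chrLen)
      while (any(diff(p) <= 0)) {          # guard against ties (measure zero)
        inner <- sort(runif(k - 2, min = 0, max = chrLen))
        p <- c(0, inner, chrLen)
      }
      chrom <- c(chrom, rep(as.character(cc), k))
      pos <- c(pos, p)
    }
    new("GeneticMap",
        marker = sprintf("m%s_%04d", chrom, unlist(lapply(base, seq_len))),
        chrom = chrom, pos = pos)
  })
}

#' Simulate RIL genotypes along a genetic map
#'
#' Final-generation recombinant inbred lines are simulated directly as a
#' two-state Markov chain over \{-1, +1\} along each chromosome: the first
#' marker is +1 or -1 with probability 1/2 and adjacent markers switch with
#' the Haldane-Waddington selfed-RIL probability R = 2r/(1 + 2r), where r is
#' the Haldane recombination fraction for the inter-marker distance. +1 codes
#' the common-parent homozygote, -1 the diverse-parent homozygote; residual
#' heterozygosity is not simulated.
#'
#' @param map a \linkS4class{GeneticMap}.
#' @param nLines number of lines (>= 1).
#' @param seed integer seed.
#' @param popId population identifier.
#' @param parents length-2 character: common parent then diverse parent.
#' @return a \linkS4class{RILPopulation}.
#' @export
simulateRILGenotypes <- function(map, nLines, seed = 1, popId = "pop1",
                                 parents = c("B73", paste0("P_", popId))) {
  stopifnot(is(map, "GeneticMap"), nLines >= 1)
  withSeed(seed, {
    k <- length(map@marker)
    geno <- matrix(0, nLines, k)
    for (ch in unique(map@chrom)) {
      idx <- which(map@chrom == ch)
      d <- diff(map@pos[idx])
      R <- rilSwitchProb(d)
      g <- matrix(0, nLines, length(idx))
      g[, 1] <- ifelse(runif(nLines) < 0.5, 1, -1)
      if (length(idx) > 1) {
        sw <- matrix(runif(nLines * (length(idx) - 1)), nLines) <
          matrix(R, nLines, length(idx) - 1, byrow = TRUE)
        for (j in 2:length(idx))
          g[, j] <- g[, j - 1] * ifelse(sw[, j - 1], -1, 1)
      }
      geno[, idx] <- g
    }
    colnames(geno) <- map@marker
    new("RILPopulation", popId = as.character(popId),
        parents = parents,
        lineIds = sprintf("%s_l%04d", popId, seq_len(nLines)),
        geno = geno)
  })
}

#' Simulate a full NAM panel
#'
#' A set of biparental RIL populations sharing one genetic map and a common
#' parent. Defaults follow the scale of a maize NAM panel: 25 populations of
#' 165 lines each.
#'
#' @param map a \linkS4class{GeneticMap}; simulated with defaults when
#'   missing.
#' @param nPop number of populations.
#' @param linesPerPop lines per population (recycled to length \code{nPop}).
#' @param seed integer master seed; population genotypes draw from derived
#'   sub-seeds.
#' @param commonParent label of the shared parent.
#' @return a \linkS4class{NAMPanel}.
#' @export
simulateNAMPanel <- function(map = simulateMap(seed = seed), nPop = 25,
                             linesPerPop = 165, seed = 1,
                             commonParent = "B73") {
  nl <- rep_len(linesPerPop, nPop)
  seeds <- splitSeed(seed, nPop)
  pops <- lapply(seq_len(nPop), function(i) {
    pid <- sprintf("pop%02d", i)
    simulateRILGenotypes(map, nl[i], seed = seeds[i], popId = pid,
                         parents = c(commonParent, paste0("P_", pid)))
  })
  new("NAMPanel", map = map, populations = pops)
}

# PSD square root via eigendecomposition (chol fails on singular targets).
psdSqrt <- function(S) {
  e <- eigen((S + t(S)) / 2, symmetric = TRUE)
  e$vectors %*% (sqrt(pmax(e$values, 0)) * t(e$vectors))
}

#' Define a polygenic multi-environment trait architecture
#'
#' QTL are placed at randomly chosen marker positions and their
#' environment-specific additive effects are drawn from a zero-mean
#' multivariate normal, then rescaled so the realized line-level genetic
#' covariance across environments equals the target G0: the raw draws are
#' whitened against the cross-product of the (centred) QTL genotypes and
#' coloured by the Cholesky factor of G0. Per-environment line-mean
#' heritability is therefore h2 = G0_ee / (G0_ee + R0_ee), with the defaults
#' targeting 0.74.
#'
#' @param panel a \linkS4class{NAMPanel}.
#' @param nEnv number of environments (ignored when \code{G0} is supplied).
#' @param nQTL number of QTL; 0 gives a purely non-genetic trait.
#' @param geneticCorr common genetic correlation between environments.
#' @param residualCorr common residual correlation between environments.
#' @param h2 per-environment line-mean heritability target.
#' @param geneticVar per-environment genetic variance.
#' @param G0,R0 explicit m x m targets overriding the scalar parameters.
#' @param muEnv environment means (default 10, 10.5, ...).
#' @param popInterceptSD standard deviation of population-by-environment
#'   intercept deviations (trait units).
#' @param seed integer seed.
#' @param qtlIndex optional explicit marker indices for the QTL.
#' @param effects optional explicit (nQTL x m) effect matrix; when supplied no
#'   rescaling is done (used to plant QTL of known effect).
#' @return a \linkS4class{TraitArchitecture}.
#' @export
traitArchitecture <- function(panel, nEnv = 4, nQTL = 70,
                              geneticCorr = 0.77, residualCorr = 0.31,
                              h2 = 0.74, geneticVar = 1,
                              G0 = NULL, R0 = NULL, muEnv = NULL,
                              popInterceptSD = 0.5, seed = 1,
                              qtlIndex = NULL, effects = NULL) {
  stopifnot(is(panel, "NAMPanel"), nQTL >= 0)
  if (is.null(G0)) {
    G0 <- matrix(geneticCorr * geneticVar, nEnv, nEnv)
    diag(G0) <- geneticVar
  }
  m <- nrow(G0)
  if (is.null(R0)) {
    ev <- geneticVar * (1 - h2) / h2
    R0 <- matrix(residualCorr * ev, m, m)
    diag(R0) <- ev
  }
  if (!isPSD(G0) || !isPSD(R0))
    stop("G0 and R0 must be symmetric positive semi-definite")
  if (is.null(muEnv)) muEnv <- 10 + 0.5 * (seq_len(m) - 1)
  envNames <- paste0("E", seq_len(m))
  k <- length(panel@map@marker)
  nPop <- length(panel@populations)
  seeds <- splitSeed(seed, 4)
  if (is.null(qtlIndex) && nQTL > 0)
    qtlIndex <- withSeed(seeds[1], sort(sample.int(k, nQTL)))
  qtlIndex <- as.integer(qtlIndex)
  nQTL <- length(qtlIndex)
  if (is.null(effects)) {
    if (nQTL == 0) {
      effects <- matrix(0, 0, m)
    } else {
      # iid effect rows with covariance G0/s, s the summed QTL genotype
      # variance, give realized genetic covariance ~ G0; a final m x m
      # rotation pins the realized line-level covariance to G0 exactly
      Q <- genotypes(panel)[, qtlIndex, drop = FALSE]
      s <- sum(apply(Q, 2, var))
      raw <- withSeed(seeds[2], matrix(rnorm(nQTL * m), nQTL, m))
      effects <- raw %*% psdSqrt(G0 / max(s, 1e-12))
      S <- cov(Q %*% effects)
      ok <- nQTL >= m &&
        min(eigen(S, symmetric = TRUE, only.values = TRUE)$values) >
          1e-10 * max(diag(S))
      if (ok) {
        Tm <- solve(chol(S)) %*% chol(projectPSD(G0, 1e-12 * max(diag(G0))))
        effects <- effects %*% Tm
      }
    }
  } else {
    effects <- as.matrix(effects)
    if (nrow(effects) != nQTL || (nQTL > 0 && ncol(effects) != m))
      stop("effects must be nQTL x m")
  }
  intercepts <- withSeed(seeds[3],
    matrix(rnorm(nPop * m, sd = popInterceptSD), nPop, m))
  rownames(intercepts) <- vapply(panel@populations, slot, character(1), "popId")
  new("TraitArchitecture", qtlIndex = qtlIndex, effects = effects,
      intercepts = intercepts, muEnv = muEnv, G0 = G0, R0 = R0,
      envNames = envNames)
}

#' True breeding values implied by an architecture
#'
#' The additive genetic value of every line in every environment,
#' \eqn{g_{ie} = \sum_j q_{ij} a_{je}} over the architecture's QTL.
#'
#' @param panel a \linkS4class{NAMPanel}.
#' @param architecture a \linkS4class{TraitArchitecture}.
#' @return numeric matrix (lines x environments).
#' @export
trueBreedingValues <- function(panel, architecture) {
  n <- length(lineIds(panel))
  m <- length(architecture@muEnv)
  if (length(architecture@qtlIndex) == 0)
    g <- matrix(0, n, m)
  else
    g <- genotypes(panel)[, architecture@qtlIndex, drop = FALSE] %*%
      architecture@effects
  dimnames(g) <- list(lineIds(panel), architecture@envNames)
  g
}

#' Simulate multi-environment phenotypes
#'
#' For line i of population p in environment e,
#' \eqn{y_{ie} = \mu_e + b_{pe} + \sum_j q_{ij} a_{je} + \epsilon_{ie}}, with
#' residual rows drawn independently per line from N(0, R0). Generation is
#' reproducible bit-for-bit given (panel, architecture, seed).
#'
#' @param panel a \linkS4class{NAMPanel}.
#' @param architecture a \linkS4class{TraitArchitecture} whose targets match
#'   the panel (intercept rows = populations).
#' @param seed integer seed for the residual draws.
#' @return a complete \linkS4class{PhenotypeTable} (no missing cells).
#' @export
simulatePhenotypes <- function(panel, architecture, seed = 1) {
  stopifnot(is(panel, "NAMPanel"), is(architecture, "TraitArchitecture"))
  if (!isPSD(architecture@G0) || !isPSD(architecture@R0))
    stop("G0 and R0 must be positive semi-definite")
  if (nrow(architecture@intercepts) != length(panel@populations))
    stop("architecture intercepts do not match the panel's populations")
  if (length(architecture@qtlIndex) > 0 &&
      max(architecture@qtlIndex) > length(panel@map@marker))
    stop("architecture QTL indices exceed the panel's marker count")
  m <- length(architecture@muEnv)
  ids <- lineIds(panel)
  pops <- populationIds(panel)
  n <- length(ids)
  g <- trueBreedingValues(panel, architecture)
  E <- withSeed(seed, matrix(rnorm(n * m), n, m) %*% t(psdSqrt(architecture@R0)))
  popRow <- match(pops, rownames(architecture@intercepts))
  Y <- sweep(g + E + architecture@intercepts[popRow, , drop = FALSE],
             2, architecture@muEnv, `+`)
  dimnames(Y) <- list(ids, architecture@envNames)
  new("PhenotypeTable", lineIds = ids, popIds = pops,
      env = architecture@envNames, values = unname(Y),
      mask = matrix(FALSE, n, m))
}
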