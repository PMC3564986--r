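# Composite interval mapping: expected QTL genotypes on a cM grid, stepwise
# cofactor selection, LOD profiles in single- (SE) and multi-environment (ME)
# form, permutation thresholds, QTL calling and joint effect estimation.

#' Expected QTL genotype between flanking markers
#'
#' Conditional expectation of the coded QTL genotype of a selfed RIL given
#' the closest flanking markers, under the two-state chain with the
#' Haldane-Waddington switch probability R = 2r/(1+2r). A flank coded 0 is
#' treated as missing and marginalised. At zero distance the expectation
#' equals the flanking marker's code; when the flanks disagree it is 0 at the
#' interval midpoint.
#'
#' @param leftGeno,rightGeno flanking genotype vectors in \{-1, 0, +1\};
#'   either may be NULL (chromosome end).
#' @param dLeft,dRight non-negative distances (cM) to the flanks.
#' @return numeric vector of expectations in [-1, 1].
#' @export
qtlExpectation <- function(leftGeno, rightGeno, dLeft, dRight) {
  stopifnot(dLeft >= 0, dRight >= 0)
  n <- length(leftGeno %||% rightGeno)
  lik <- function(geno, R) {
    # P(marker | Q = +1) and P(marker | Q = -1); missing flank -> 1
    if (is.null(geno)) return(list(p = rep(1, n), m = rep(1, n)))
    p <- ifelse(geno == 1, 1 - R, ifelse(geno == -1, R, 1))
    m <- ifelse(geno == -1, 1 - R, ifelse(geno == 1, R, 1))
    list(p = p, m = m)
  }
  L <- lik(leftGeno, rilSwitchProb(dLeft))
  Rl <- lik(rightGeno, rilSwitchProb(dRight))
  wp <- L$p * Rl$p
  wm <- L$m * Rl$m
  (wp - wm) / (wp + wm)
}

# Scan grid and expected QTL genotypes for a whole map. The grid is the
# union of a fixed-step lattice and the exact marker positions, so tests at
# markers use the observed codes.
.scanGrid <- function(geno, map, step) {
  chroms <- unique(map@chrom)
  outChrom <- character(0); outPos <- numeric(0)
  EQ <- NULL
  for (ch in chroms) {
    idx <- which(map@chrom == ch)
    pos <- map@pos[idx]
    grid <- sort(unique(c(seq(min(pos), max(pos), by = step), pos)))
    E <- matrix(0, nrow(geno), length(grid))
    for (g in seq_along(grid)) {
      p <- grid[g]
      ir <- findInterval(p, pos)
      if (abs(p - pos[ir]) < 1e-9) {
        left <- idx[ir]; right <- idx[ir]
        dl <- 0; dr <- 0
      } else {
        left <- idx[ir]; right <- idx[ir + 1]
        dl <- p - pos[ir]; dr <- map@pos[right] - p
      }
      E[, g] <- qtlExpectation(geno[, left], geno[, right], dl, dr)
    }
    outChrom <- c(outChrom, rep(ch, length(grid)))
    outPos <- c(outPos, grid)
    EQ <- cbind(EQ, E)
  }
  list(chrom = outChrom, pos = outPos, EQ = EQ)
}

# single-degree-of-freedom multivariate (or univariate) test of each column
# of E added to the regression of Y on base B; returns Wilks' lambda per
# column plus the error scatter of the base model
.rankOneTests <- function(Y, B, E) {
  qr0 <- qr(B)
  Yres <- qr.resid(qr0, Y)
  S0 <- crossprod(Yres)
  Eres <- qr.resid(qr0, E)
  ss <- colSums(Eres^2)
  bb <- crossprod(Eres, Yres)                      # P x m
  quad <- rowSums(bb * t(solve(S0, t(bb))))
  lambda <- 1 - quad / pmax(ss, 1e-300)
  lambda[ss < 1e-10] <- 1
  list(lambda = pmax(pmin(lambda, 1), 1e-300), rank0 = qr0$rank)
}

#' Composite interval mapping genome scan
#'
#' Scans the genome on a fixed-step cM grid (marker positions included
#' exactly). At each position the expected QTL genotype is tested in a
#' regression of the phenotypes on the fixed effects and the cofactor
#' markers, with cofactors within \code{excludeWindow} cM of the tested
#' position dropped from the model for that test. In SE mode (one phenotype
#' column) LOD = (n/2) log10(RSS0/RSS1); in ME mode LOD =
#' (n/2) log10(|S0|/|S1|) for the determinant of the residual scatter,
#' testing the 1 x m effect row jointly.
#'
#' @param Y phenotype matrix (n x m; one column for SE mode), complete.
#' @param X fixed-effect incidence.
#' @param geno marker matrix in map order.
#' @param map the \linkS4class{GeneticMap}.
#' @param cofactors integer marker indices used as background cofactors.
#' @param step scan step in cM (> 0).
#' @param mode "SE" or "ME".
#' @param excludeWindow half-width (cM) of the cofactor exclusion zone.
#' @return a \linkS4class{LODProfile}.
#' @export
cimScan <- function(Y, X, geno, map, cofactors = integer(0), step = 1,
                    mode = c("ME", "SE"), excludeWindow = 10) {
  mode <- match.arg(mode)
  Y <- as.matrix(Y)
  stopifnot(step > 0, !anyNA(Y))
  if (mode == "SE" && ncol(Y) != 1)
    stop("SE mode expects a single phenotype column")
  n <- nrow(Y)
  ctx <- .scanGrid(geno, map, step)
  P <- length(ctx$pos)
  lod <- numeric(P)
  # group scan positions by their active cofactor set
  if (length(cofactors) > 0) {
    cch <- map@chrom[cofactors]; cpos <- map@pos[cofactors]
    act <- vapply(seq_len(P), function(g) {
      excl <- cch == ctx$chrom[g] & abs(cpos - ctx$pos[g]) < excludeWindow
      paste(which(!excl), collapse = ",")
    }, character(1))
  } else act <- rep("", P)
  for (key in unique(act)) {
    sel <- which(act == key)
    keep <- if (nzchar(key)) cofactors[as.integer(strsplit(key, ",")[[1]])] else integer(0)
    B <- cbind(X, geno[, keep, drop = FALSE])
    tests <- .rankOneTests(Y, B, ctx$EQ[, sel, drop = FALSE])
    lod[sel] <- pmax(-(n / 2) * log10(tests$lambda), 0)
  }
  new("LODProfile", chrom = ctx$chrom, pos = ctx$pos, lod = lod, mode = mode,
      env = if (mode == "SE") (colnames(Y)[1] %||% "E1") else "joint")
}

#' Stepwise cofactor selection
#'
#' Forward selection adds the marker with the smallest entry p-value while it
#' is below \code{alphaEnter}, followed by backward elimination at the same
#' level. The entry test is the single-degree-of-freedom F (univariate, SE
#' mode) or Rao's F for Wilks' lambda (multivariate, ME mode); ties break by
#' map order. An empty cofactor set is a valid result.
#'
#' @param Y phenotype matrix (n x m; one column in SE mode), complete.
#' @param X fixed-effect incidence.
#' @param geno marker matrix in map order.
#' @param alphaEnter entry/stay significance level in (0, 1).
#' @param mode "SE" or "ME".
#' @param maxCofactors cap on the number of selected markers.
#' @return list with \code{indices} (integer, sorted by map order) and
#'   \code{effects} (f x m least-squares cofactor effects).
#' @export
selectCofactors <- function(Y, X, geno, alphaEnter, mode = c("ME", "SE"),
                            maxCofactors = max(10, nrow(Y) %/% 10)) {
  mode <- match.arg(mode)
  Y <- as.matrix(Y)
  stopifnot(alphaEnter > 0, alphaEnter < 1, !anyNA(Y))
  if (mode == "SE" && ncol(Y) != 1)
    stop("SE mode expects a single phenotype column")
  n <- nrow(Y); m <- ncol(Y); k <- ncol(geno)
  pvalOf <- function(lambda, qcur) {
    nu <- n - qcur - m
    if (nu <= 0) return(rep(1, length(lambda)))
    Fv <- (1 - lambda) / lambda * nu / m
    pf(Fv, m, nu, lower.tail = FALSE)
  }
  selected <- integer(0)
  repeat {
    if (length(selected) >= maxCofactors) break
    cand <- setdiff(seq_len(k), selected)
    B <- cbind(X, geno[, selected, drop = FALSE])
    tests <- .rankOneTests(Y, B, geno[, cand, drop = FALSE])
    pv <- pvalOf(tests$lambda, ncol(B))
    best <- which.min(pv)
    if (pv[best] < alphaEnter) selected <- c(selected, cand[best]) else break
  }
  # backward elimination at the same level
  repeat {
    if (length(selected) == 0) break
    pv <- vapply(seq_along(selected), function(i) {
      B <- cbind(X, geno[, selected[-i], drop = FALSE])
      tests <- .rankOneTests(Y, B, geno[, selected[i], drop = FALSE])
      pvalOf(tests$lambda, ncol(B))
    }, numeric(1))
    worst <- which.max(pv)
    if (pv[worst] >= alphaEnter) selected <- selected[-worst] else break
  }
  selected <- sort(selected)
  eff <- if (length(selected) > 0) {
    cf <- qr.coef(qr(cbind(X, geno[, selected, drop = FALSE])), Y)
    matrix(cf[ncol(X) + seq_along(selected), ], length(selected), m)
  } else matrix(0, 0, m)
  list(indices = selected, effects = eff)
}

#' Permutation LOD threshold
#'
#' Genome-wide LOD threshold as the empirical (1 - alpha) quantile of the
#' per-permutation maximum LOD. In SE mode phenotype values are shuffled
#' within each population independently; in ME mode whole multi-environment
#' rows are shuffled jointly within population so the cross-environment
#' correlation structure is preserved. Cofactors are re-selected on each
#' permuted data set under \code{cofactorRule = "reselect"}; \code{"none"}
#' scans without cofactors (much faster; identical under the null when
#' selection virtually never fires).
#'
#' @param Y phenotype matrix (one column in SE mode), complete.
#' @param X fixed-effect incidence.
#' @param geno,map markers and map.
#' @param popIds population identifier per line.
#' @param nPerm number of permutations (study default 5000; >= 100 for
#'   testing).
#' @param alpha genome-wide significance level.
#' @param mode "SE" or "ME".
#' @param cofactorRule "reselect" or "none".
#' @param alphaEnter cofactor entry level when re-selecting.
#' @param step scan step in cM.
#' @param seed integer seed; fixed seed gives an identical threshold.
#' @param excludeWindow cofactor exclusion half-width in cM.
#' @return list with \code{threshold}, \code{nPerm}, \code{alpha},
#'   \code{scheme}, and the permuted \code{maxLod} values.
#' @export
permutationThreshold <- function(Y, X, geno, map, popIds, nPerm = 5000,
                                 alpha = 0.05, mode = c("ME", "SE"),
                                 cofactorRule = c("reselect", "none"),
                                 alphaEnter = 1e-4, step = 1, seed = 1,
                                 excludeWindow = 10) {
  mode <- match.arg(mode)
  cofactorRule <- match.arg(cofactorRule)
  Y <- as.matrix(Y)
  n <- nrow(Y)
  popIdx <- split(seq_len(n), as.character(popIds))
  seeds <- splitSeed(seed, nPerm)
  fastPath <- cofactorRule == "none"
  if (fastPath) {
    ctx <- .scanGrid(geno, map, step)
    qr0 <- qr(X)
    Eres <- qr.resid(qr0, ctx$EQ)
    ss <- pmax(colSums(Eres^2), 1e-300)
    bad <- colSums(Eres^2) < 1e-10
  }
  maxLod <- vapply(seq_len(nPerm), function(b) {
    Yp <- withSeed(seeds[b], {
      Yp <- Y
      for (ii in popIdx) {
        if (mode == "SE") Yp[ii, 1] <- Y[sample(ii), 1]
        else Yp[ii, ] <- Y[sample(ii), , drop = FALSE]
      }
      Yp
    })
    if (fastPath) {
      Yres <- qr.resid(qr0, Yp)
      S0 <- crossprod(Yres)
      bb <- crossprod(Eres, Yres)
      quad <- rowSums(bb * t(solve(S0, t(bb))))
      lambda <- pmax(1 - quad / ss, 1e-300)
      lambda[bad] <- 1
      max(pmax(-(n / 2) * log10(lambda), 0))
    } else {
      cof <- selectCofactors(Yp, X, geno, alphaEnter, mode)
      max(cimScan(Yp, X, geno, map, cof$indices, step, mode,
                  excludeWindow)@lod)
    }
  }, numeric(1))
  list(threshold = as.numeric(quantile(maxLod, 1 - alpha, type = 1)),
       nPerm = nPerm, alpha = alpha,
       scheme = paste0(mode, "-within-population"), maxLod = maxLod)
}

#' Call QTL from a LOD profile
#'
#' Contiguous above-threshold runs of the scan grid form regions; runs on the
#' same chromosome separated by less than \code{mergeWithin} cM are merged.
#' Each region yields one call at its maximum LOD, ties broken by the
#' leftmost position.
#'
#' @param profile a \linkS4class{LODProfile}.
#' @param threshold LOD threshold (>= 0).
#' @param mergeWithin minimum separation (cM) between distinct regions.
#' @return data.frame with columns chrom, pos, lod (possibly zero rows).
#' @export
callQTL <- function(profile, threshold, mergeWithin = 20) {
  stopifnot(threshold >= 0)
  out <- data.frame(chrom = character(0), pos = numeric(0), lod = numeric(0))
  for (ch in unique(profile@chrom)) {
    sel <- profile@chrom == ch
    pos <- profile@pos[sel]; lod <- profile@lod[sel]
    above <- which(lod >= threshold)
    if (length(above) == 0) next
    gaps <- which(diff(pos[above]) >= mergeWithin)
    starts <- c(1, gaps + 1); ends <- c(gaps, length(above))
    for (s in seq_along(starts)) {
      ii <- above[starts[s]:ends[s]]
      peak <- ii[which.max(lod[ii])]       # which.max -> leftmost tie
      out <- rbind(out, data.frame(chrom = ch, pos = pos[peak],
                                   lod = lod[peak]))
    }
  }
  out
}

# expected QTL genotypes at arbitrary map positions for a genotype matrix
.eqAt <- function(geno, map, chrom, pos) {
  E <- matrix(0, nrow(geno), length(pos))
  for (g in seq_along(pos)) {
    idx <- which(map@chrom == chrom[g])
    mp <- map@pos[idx]
    ir <- findInterval(pos[g], mp, all.inside = TRUE)
    if (abs(pos[g] - mp[ir]) < 1e-9) {
      E[, g] <- qtlExpectation(geno[, idx[ir]], geno[, idx[ir]], 0, 0)
    } else if (ir < length(idx) && pos[g] > mp[ir]) {
      E[, g] <- qtlExpectation(geno[, idx[ir]], geno[, idx[ir + 1]],
                               pos[g] - mp[ir], mp[ir + 1] - pos[g])
    } else {
      E[, g] <- qtlExpectation(geno[, idx[ir]], NULL, abs(pos[g] - mp[ir]), 0)
    }
  }
  E
}

#' Joint estimation of called QTL effects
#'
#' Multivariate multiple regression of the phenotypes on all called QTL
#' simultaneously (expected genotypes at the called positions) with the
#' population fixed effects. Collinear QTL columns fall back to a flagged
#' minimum-norm solution. The result drives QTL-based prediction.
#'
#' @param calls data.frame from \code{\link{callQTL}}.
#' @param Y phenotype matrix, complete.
#' @param X fixed-effect incidence (leading ones column).
#' @param geno,map training markers and map.
#' @return list with \code{mu} (per-environment overall mean),
#'   \code{effects} (nQTL x m), \code{calls}, and \code{singular} flag.
#' @export
estimateQTLEffects <- function(calls, Y, X, geno, map) {
  Y <- as.matrix(Y)
  m <- ncol(Y)
  if (nrow(calls) == 0) {
    cf <- qr.coef(qr(X), Y)
    mu <- if (is.matrix(cf)) cf[1, ] else cf[1]
    return(list(mu = setNames(as.numeric(mu), colnames(Y)),
                effects = matrix(0, 0, m), calls = calls, singular = FALSE))
  }
  E <- .eqAt(geno, map, calls$chrom, calls$pos)
  B <- cbind(X, E)
  sol <- solveMaybeSingular(crossprod(B), crossprod(B, Y))
  cf <- matrix(sol$x, ncol(B), m)
  list(mu = setNames(cf[1, ], colnames(Y)),
       effects = cf[ncol(X) + seq_len(nrow(calls)), , drop = FALSE],
       calls = calls, singular = sol$singular)
}

#' Predict breeding values from called QTL
#'
#' QTL-based analogue of the genome-wide prediction equation: overall mean
#' plus expected QTL genotypes times their estimated effects. With zero calls
#' the prediction is the overall mean for every line.
#'
#' @param qfit result of \code{\link{estimateQTLEffects}}.
#' @param geno validation genotype matrix (map order).
#' @param map the shared \linkS4class{GeneticMap}.
#' @param environment environment label (column of the training Y).
#' @return numeric vector of predictions.
#' @export
predictQTL <- function(qfit, geno, map, environment) {
  e <- match(environment, names(qfit$mu))
  if (is.na(e)) stop("environment label not in QTL fit: ", environment)
  if (nrow(qfit$calls) == 0) return(rep(qfit$mu[e], nrow(geno)))
  E <- .eqAt(geno, map, qfit$calls$chrom, qfit$calls$pos)
  drop(qfit$mu[e] + E %*% qfit$effects[, e])
}

#' Iterative imputation of missing phenotypes
#'
#' EM-style completion for unbalanced (CV2) records: each missing cell is
#' replaced by its conditional expectation given the line's observed
#' environments under a multivariate-normal model whose mean is the current
#' fixed-effect fit and whose covariance is either supplied (e.g. G0 + R0
#' from REML) or taken as the residual covariance of the current completed
#' data. Iterates until the largest fill change drops below \code{tol}.
#'
#' @param Y n x m phenotype matrix with NA for missing cells; no line may
#'   miss every environment.
#' @param X fixed-effect incidence.
#' @param Sigma optional fixed m x m covariance for the conditional fill.
#' @param tol convergence tolerance on the maximum absolute fill change.
#' @param maxit maximum iterations (non-convergence is flagged, the last
#'   iterate returned).
#' @return list with completed \code{Y}, \code{iterations}, \code{converged}.
#' @export
imputePhenotypes <- function(Y, X, Sigma = NULL, tol = 1e-4, maxit = 50) {
  Y <- as.matrix(Y)
  miss <- is.na(Y)
  if (!any(miss))
    return(list(Y = Y, iterations = 0, converged = TRUE))
  if (any(rowSums(!miss) == 0))
    stop("no line may be missing all environments")
  m <- ncol(Y)
  Ycur <- Y
  for (e in seq_len(m)) Ycur[miss[, e], e] <- mean(Y[, e], na.rm = TRUE)
  converged <- FALSE; it <- 0
  while (it < maxit) {
    it <- it + 1
    cf <- qr.coef(qr(X), Ycur)
    Mu <- X %*% cf
    S <- if (is.null(Sigma)) cov(Ycur - Mu) else Sigma
    S <- projectPSD(S, 1e-10 * max(diag(S)))
    Ynew <- Ycur
    for (l in which(rowSums(miss) > 0)) {
      o <- which(!miss[l, ]); mm <- which(miss[l, ])
      Soo <- S[o, o, drop = FALSE] +
        diag(1e-10 * max(diag(S)), length(o))
      Ynew[l, mm] <- Mu[l, mm] + S[mm, o, drop = FALSE] %*%
        solve(Soo, (Y[l, o] - Mu[l, o]))
    }
    delta <- max(abs(Ynew[miss] - Ycur[miss]))
    Ycur <- Ynew
    if (delta < tol) { converged <- TRUE; break }
  }
  list(Y = Ycur, iterations = it, converged = converged)
}
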