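test_that("univariate REML matches a dense grid-search oracle on a toy", {
  set.seed(41)
  n <- 5
  Z <- matrix(sample(c(-1, 1), n * 6, TRUE), n, 6)
  A <- computeGRM(Z)
  X <- matrix(1, n, 1)
  y <- rnorm(n, sd = 1.3)
  fit <- remlUnivariate(y, X, A)
  # brute-force 2-D grid over (sigma_g^2, sigma_e^2)
  grid <- expand.grid(sg = seq(0.01, 4, length.out = 60),
                      se = seq(0.01, 4, length.out = 60))
  ll <- mapply(function(sg, se) denseRemlLogLik(y, X, A, sg, se),
               grid$sg, grid$se)
  best <- grid[which.max(ll), ]
  step <- c(diff(seq(0.01, 4, length.out = 60))[1])
  # the optimiser's maximum must dominate the whole grid and sit within one
  # grid cell of the grid argmax (when interior)
  expect_gte(fit$loglik, max(ll) - 1e-6)
  if (fit$geneticVar < 4 && fit$residualVar < 4) {
    expect_lt(abs(fit$geneticVar - best$sg), 2 * step)
    expect_lt(abs(fit$residualVar - best$se), 2 * step)
  }
  # reported log-likelihood agrees with the dense oracle at the estimate
  expect_equal(fit$loglik,
               denseRemlLogLik(y, X, A, fit$geneticVar, fit$residualVar),
               tolerance = 1e-6)
})

test_that("constant phenotypes drive both variances to the floor", {
  Z <- matrix(sample(c(-1, 1), 40, TRUE), 8, 5)
  fit <- remlUnivariate(rep(2, 8), matrix(1, 8, 1), computeGRM(Z))
  expect_lt(fit$geneticVar, 1e-6)
  expect_lt(fit$residualVar, 1e-6)
})

test_that("univariate REML recovers heritability on generator output", {
  h2s <- vapply(1:50, function(i) {
    mp <- simulateMap(nChrom = 3, totalLength = 450, nMarkers = 150,
                      seed = 700 + i)
    pn <- simulateNAMPanel(mp, nPop = 2, linesPerPop = 250, seed = 800 + i)
    ar <- traitArchitecture(pn, nEnv = 1, nQTL = 50, h2 = 0.7, seed = 900 + i)
    ph <- simulatePhenotypes(pn, ar, seed = 1000 + i)
    remlUnivariate(phenoValues(ph)[, 1],
                   populationDesign(populationIds(pn)),
                   computeGRM(genotypes(pn)))$h2
  }, numeric(1))
  expect_lt(abs(mean(h2s) - 0.7), 0.05)
})

test_that("bivariate REML behaves at the duplicated-trait and null limits", {
  panel <- smallPanel(nPop = 2, linesPerPop = 150, nChrom = 3,
                      totalLength = 300, nMarkers = 90, seed = 51)
  X <- populationDesign(populationIds(panel))
  A <- computeGRM(genotypes(panel))
  ar <- traitArchitecture(panel, nEnv = 1, nQTL = 40, h2 = 0.7, seed = 52)
  ph <- simulatePhenotypes(panel, ar, seed = 53)
  y <- phenoValues(ph)[, 1]

  # duplicated trait: genetic correlation -> 1
  fit <- remlBivariate(cbind(y, y), X, A)
  expect_gt(fit$G0[1, 2] / sqrt(fit$G0[1, 1] * fit$G0[2, 2]), 0.98)

  # independent traits: correlations near 0 over replicate means at n = 1000
  panelN <- simulateNAMPanel(simulateMap(3, 500, 250, seed = 55), nPop = 2,
                             linesPerPop = 500, seed = 56)
  XN <- populationDesign(populationIds(panelN))
  AN <- computeGRM(genotypes(panelN))
  ests <- sapply(1:6, function(i) {
    ar2 <- traitArchitecture(panelN, nEnv = 2, nQTL = 60, geneticCorr = 0,
                             residualCorr = 0, h2 = 0.7, seed = 60 + i)
    ph2 <- simulatePhenotypes(panelN, ar2, seed = 70 + i)
    f <- remlBivariate(phenoValues(ph2), XN, AN)
    c(f$G0[1, 2] / sqrt(f$G0[1, 1] * f$G0[2, 2]),
      f$R0[1, 2] / sqrt(f$R0[1, 1] * f$R0[2, 2]))
  })
  expect_lt(abs(mean(ests[1, ])), 0.1)
  expect_lt(abs(mean(ests[2, ])), 0.1)
})

test_that("bivariate REML recovers generator correlations", {
  ests <- sapply(1:4, function(i) {
    mp <- simulateMap(nChrom = 3, totalLength = 500, nMarkers = 250,
                      seed = 80 + i)
    pn <- simulateNAMPanel(mp, nPop = 2, linesPerPop = 500, seed = 90 + i)
    ar <- traitArchitecture(pn, nEnv = 2, nQTL = 60, geneticCorr = 0.8,
                            residualCorr = 0.3, h2 = 0.74, seed = 100 + i)
    ph <- simulatePhenotypes(pn, ar, seed = 110 + i)
    f <- remlBivariate(phenoValues(ph), populationDesign(populationIds(pn)),
                       computeGRM(genotypes(pn)))
    c(f$G0[1, 2] / sqrt(f$G0[1, 1] * f$G0[2, 2]),
      f$R0[1, 2] / sqrt(f$R0[1, 1] * f$R0[2, 2]))
  })
  expect_lt(abs(mean(ests[1, ]) - 0.8), 0.1)
  expect_lt(abs(mean(ests[2, ]) - 0.3), 0.1)
})

test_that("multivariate EM-REML has a monotone restricted log-likelihood", {
  panel <- smallPanel(nPop = 2, linesPerPop = 120, nChrom = 3,
                      totalLength = 300, nMarkers = 90, seed = 121)
  ar <- traitArchitecture(panel, nEnv = 3, nQTL = 50, geneticCorr = 0.7,
                          residualCorr = 0.3, h2 = 0.7, seed = 122)
  ph <- simulatePhenotypes(panel, ar, seed = 123)
  X <- populationDesign(populationIds(panel))
  A <- computeGRM(genotypes(panel))
  est <- remlMultivariate(phenoValues(ph), X, A, keepPath = TRUE)
  ll <- attr(est, "llPath")
  expect_true(all(diff(ll) > -1e-8))
  expect_true(est@converged)

  # unbalanced (observed-cell) path is monotone too
  Y <- phenoValues(ph)
  set.seed(124)
  Y[sample(length(Y), length(Y) * 0.2)] <- NA
  Y <- Y[rowSums(!is.na(Y)) > 0, ]
  keep <- match(rownames(Y), lineIds(panel))
  estU <- remlMultivariate(Y, populationDesign(populationIds(panel)[keep]),
                           A[keep, keep], keepPath = TRUE, maxit = 60)
  expect_true(all(diff(attr(estU, "llPath")) > -1e-8))
})

test_that("balanced and observed-cell EM paths agree on complete data", {
  panel <- smallPanel(nPop = 2, linesPerPop = 40, nChrom = 2,
                      totalLength = 150, nMarkers = 40, seed = 131)
  ar <- traitArchitecture(panel, nEnv = 2, nQTL = 30, geneticCorr = 0.6,
                          residualCorr = 0.2, h2 = 0.6, seed = 132)
  ph <- simulatePhenotypes(panel, ar, seed = 133)
  X <- populationDesign(populationIds(panel))
  A <- computeGRM(genotypes(panel))
  Y <- phenoValues(ph)
  init <- list(G0 = diag(0.4, 2), R0 = diag(0.4, 2))
  bal <- remlMultivariate(Y, X, A, init = init, maxit = 25, keepPath = TRUE)
  Yna <- Y; Yna[1, 1] <- NA      # force the observed-cell path
  # compare the two code paths' likelihoods on identical complete data by
  # evaluating one EM iteration: run the dense path on the same data
  dense <- namGP:::.emRemlUnbalanced(Y, X, A, init$G0, init$R0, tol = 1e-6,
                                     maxit = 25)
  expect_equal(attr(bal, "llPath")[1:10], dense$llPath[1:10], tolerance = 1e-6)
  expect_equal(bal@G0, dense$G0, tolerance = 1e-4)
  expect_equal(bal@R0, dense$R0, tolerance = 1e-4)
})

test_that("multivariate REML with m = 1 reduces to the univariate fit", {
  panel <- smallPanel(nPop = 2, linesPerPop = 80, seed = 141)
  ar <- traitArchitecture(panel, nEnv = 1, nQTL = 15, h2 = 0.6, seed = 142)
  ph <- simulatePhenotypes(panel, ar, seed = 143)
  X <- populationDesign(populationIds(panel))
  A <- computeGRM(genotypes(panel))
  uni <- remlUnivariate(phenoValues(ph)[, 1], X, A)
  multi <- remlMultivariate(phenoValues(ph)[, 1, drop = FALSE], X, A)
  expect_equal(multi@G0[1, 1], uni$geneticVar, tolerance = 1e-8)
  expect_equal(multi@R0[1, 1], uni$residualVar, tolerance = 1e-8)
  expect_equal(multi@loglik, uni$loglik, tolerance = 1e-8)
})

test_that("EM is stationary at its optimum", {
  panel <- smallPanel(nPop = 2, linesPerPop = 200, nChrom = 3,
                      totalLength = 400, nMarkers = 150, seed = 151)
  ar <- traitArchitecture(panel, nEnv = 2, nQTL = 50, geneticCorr = 0.8,
                          seed = 152)
  ph <- simulatePhenotypes(panel, ar, seed = 153)
  X <- populationDesign(populationIds(panel))
  A <- computeGRM(genotypes(panel))
  est <- remlMultivariate(phenoValues(ph), X, A)
  re <- remlMultivariate(phenoValues(ph), X, A,
                         init = list(G0 = est@G0, R0 = est@R0),
                         keepPath = TRUE, maxit = 3)
  ll <- attr(re, "llPath")
  expect_lt(abs(diff(ll)[1]), 1e-3)
})

test_that("covariance structures are imposed, idempotent and commuting", {
  G0 <- matrix(c(1, .6, .6, .9), 2); R0 <- matrix(c(.4, .1, .1, .5), 2)
  est <- new("CovarianceEstimate", G0 = G0, R0 = R0, structure = "UG-UR",
             loglik = -1, iterations = 5, converged = TRUE)
  expect_equal(applyStructure(est, "UG-UR")@G0, G0)
  sgsr <- applyStructure(est, "SG-SR")
  expect_equal(sgsr@G0, diag(diag(G0), 2))
  expect_equal(sgsr@R0, diag(diag(R0), 2))
  # diagonals never modified
  expect_equal(diag(applyStructure(est, "SG-UR")@G0), diag(G0))
  expect_equal(applyStructure(est, "SG-UR")@R0, R0)
  # idempotent and commuting
  expect_equal(applyStructure(applyStructure(est, "SG-SR"), "SG-SR")@G0,
               sgsr@G0)
  expect_equal(applyStructure(applyStructure(est, "SG-UR"), "UG-SR")@G0,
               applyStructure(applyStructure(est, "UG-SR"), "SG-UR")@G0)
  expect_error(applyStructure(est, "XX-YY"), "unknown")
})

test_that("multivariate REML recovers the generator's G0 and R0", {
  # parameter recovery at moderate scale (the acceptance suite runs the
  # full-size version): 4 panels, n = 600, m = 3
  res <- sapply(1:4, function(i) {
    mp <- simulateMap(nChrom = 4, totalLength = 500, nMarkers = 250,
                      seed = 160 + i)
    pn <- simulateNAMPanel(mp, nPop = 3, linesPerPop = 200, seed = 170 + i)
    ar <- traitArchitecture(pn, nEnv = 3, nQTL = 60, geneticCorr = 0.77,
                            residualCorr = 0.31, h2 = 0.74, seed = 180 + i)
    ph <- simulatePhenotypes(pn, ar, seed = 190 + i)
    A <- computeGRM(genotypes(pn))
    est <- remlMultivariate(phenoValues(ph),
                            populationDesign(populationIds(pn)), A)
    gc <- cov2cor(geneticCovariance(est))
    rc <- cov2cor(residualCovariance(est))
    c(gcor = mean(gc[upper.tri(gc)]), rcor = mean(rc[upper.tri(rc)]),
      gvar = mean(diag(geneticCovariance(est))) * mean(diag(A)),
      rvar = mean(diag(residualCovariance(est))))
  })
  expect_lt(abs(mean(res["gcor", ]) - 0.77), 0.1)
  expect_lt(abs(mean(res["rcor", ]) - 0.31), 0.1)
  expect_lt(abs(mean(res["gvar", ]) - 1), 0.15)
  expect_lt(abs(mean(res["rvar", ]) / (0.26 / 0.74) - 1), 0.15)
})
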