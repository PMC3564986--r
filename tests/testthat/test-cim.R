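test_that("expected QTL genotypes follow the two-state chain conditionals", {
  # at the left marker the expectation is the marker code
  expect_equal(qtlExpectation(c(1, -1), c(-1, 1), 0, 12), c(1, -1))
  # both flanks +1 at the midpoint of a 20 cM interval: closed form
  R <- namGP:::rilSwitchProb(10)
  expected <- ((1 - R)^2 - R^2) / ((1 - R)^2 + R^2)
  expect_equal(qtlExpectation(1, 1, 10, 10), expected)
  # disagreeing flanks at the exact midpoint: symmetry gives 0
  expect_equal(qtlExpectation(1, -1, 7, 7), 0)
  # a 0-coded flank is marginalised: only the other flank informs
  expect_equal(qtlExpectation(0, 1, 5, 5), qtlExpectation(NULL, 1, 0, 5))
  # expectations stay inside [-1, 1] and shrink with distance
  e1 <- qtlExpectation(1, 1, 1, 1); e2 <- qtlExpectation(1, 1, 30, 30)
  expect_true(e1 > e2 && e2 > 0 && e1 <= 1)
})

test_that("the scan localises a perfect signal and SE equals ME at m = 1", {
  map <- simulateMap(nChrom = 2, totalLength = 200, nMarkers = 40, seed = 201)
  panel <- simulateNAMPanel(map, nPop = 1, linesPerPop = 200, seed = 202)
  Z <- genotypes(panel); X <- populationDesign(populationIds(panel))
  set.seed(203)
  y <- matrix(Z[, 25] + rnorm(200, 0, 0.05))
  prof <- cimScan(y, X, Z, map, mode = "SE", step = 2)
  pk <- which.max(prof@lod)
  expect_equal(prof@chrom[pk], chromosomes(map)[[25]])
  expect_lt(abs(prof@pos[pk] - positions(map)[[25]]), 2 + 1e-9)
  expect_true(all(prof@lod >= 0))

  profME <- cimScan(y, X, Z, map, mode = "ME", step = 2)
  expect_lt(max(abs(prof@lod - profME@lod)), 1e-8)

  # LOD at a marker equals (n/2) log10(RSS0/RSS1) computed directly
  rss0 <- sum(qr.resid(qr(X), y)^2)
  rss1 <- sum(qr.resid(qr(cbind(X, Z[, 25])), y)^2)
  at <- which(prof@chrom == chromosomes(map)[[25]] &
                abs(prof@pos - positions(map)[[25]]) < 1e-9)
  expect_equal(prof@lod[at], (200 / 2) * log10(rss0 / rss1),
               tolerance = 1e-8)
  expect_lte(rss1, rss0)
})

test_that("scan peaks land near a planted QTL of modest effect", {
  map <- simulateMap(nChrom = 2, totalLength = 200, nMarkers = 60, seed = 211)
  hits <- vapply(1:100, function(i) {
    panel <- simulateNAMPanel(map, nPop = 1, linesPerPop = 200,
                              seed = 300 + i)
    Z <- genotypes(panel)
    qtl <- 30
    set.seed(400 + i)
    # h2_QTL = 0.2: var(q) = 1 so effect = sqrt(0.2/0.8) relative to noise 1
    y <- matrix(sqrt(0.25) * Z[, qtl] + rnorm(200))
    prof <- cimScan(y, populationDesign(rep("p", 200)), Z, map,
                    mode = "SE", step = 2)
    pk <- which.max(prof@lod)
    prof@chrom[pk] == chromosomes(map)[[qtl]] &&
      abs(prof@pos[pk] - positions(map)[[qtl]]) <= 10
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("stepwise cofactor selection is calibrated and powerful", {
  map <- simulateMap(nChrom = 2, totalLength = 160, nMarkers = 50, seed = 221)
  panel <- simulateNAMPanel(map, nPop = 1, linesPerPop = 250, seed = 222)
  Z <- genotypes(panel); X <- populationDesign(populationIds(panel))

  # null calibration: with alpha = 1e-4 selections are near zero
  set.seed(223)
  nsel <- vapply(1:40, function(i)
    length(selectCofactors(matrix(rnorm(250)), X, Z, 1e-4,
                           mode = "SE")$indices), numeric(1))
  expect_lt(mean(nsel), 0.15)

  # power: a QTL explaining ~20% of variance at marker 37 is found first
  found <- vapply(1:60, function(i) {
    pn <- simulateNAMPanel(map, nPop = 1, linesPerPop = 250, seed = 500 + i)
    Zi <- genotypes(pn)
    set.seed(600 + i)
    y <- matrix(0.5 * Zi[, 37] + rnorm(250))
    sel <- selectCofactors(y, X, Zi, 1e-4, mode = "SE")$indices
    length(sel) >= 1 &&
      any(abs(positions(map)[sel] - positions(map)[[37]]) < 3 &
            chromosomes(map)[sel] == chromosomes(map)[[37]])
  }, logical(1))
  expect_gte(mean(found), 0.95)

  # vanishing entry level: empty set
  set.seed(224)
  expect_length(selectCofactors(matrix(rnorm(250)), X, Z, 1e-12,
                                mode = "SE")$indices, 0)
})

test_that("permutation thresholds are deterministic with quantile edge cases", {
  map <- simulateMap(nChrom = 2, totalLength = 120, nMarkers = 30, seed = 231)
  panel <- simulateNAMPanel(map, nPop = 2, linesPerPop = 80, seed = 232)
  Z <- genotypes(panel); X <- populationDesign(populationIds(panel))
  set.seed(233)
  y <- matrix(rnorm(160))
  pid <- populationIds(panel)
  t1 <- permutationThreshold(y, X, Z, map, pid, nPerm = 60, mode = "SE",
                             cofactorRule = "none", step = 4, seed = 7)
  t2 <- permutationThreshold(y, X, Z, map, pid, nPerm = 60, mode = "SE",
                             cofactorRule = "none", step = 4, seed = 7)
  expect_identical(t1$threshold, t2$threshold)
  ta <- permutationThreshold(y, X, Z, map, pid, nPerm = 60, alpha = 1,
                             mode = "SE", cofactorRule = "none", step = 4,
                             seed = 7)
  expect_equal(ta$threshold, min(t1$maxLod))
  # ME permutations preserve rows; threshold must also be reproducible
  Y2 <- cbind(y, matrix(rnorm(160)))
  m1 <- permutationThreshold(Y2, X, Z, map, pid, nPerm = 40, mode = "ME",
                             cofactorRule = "none", step = 4, seed = 8)
  m2 <- permutationThreshold(Y2, X, Z, map, pid, nPerm = 40, mode = "ME",
                             cofactorRule = "none", step = 4, seed = 8)
  expect_identical(m1$threshold, m2$threshold)
})

test_that("QTL calling merges regions and breaks ties leftmost", {
  prof <- new("LODProfile", chrom = rep("1", 11), pos = seq(0, 100, 10),
              lod = c(1, 5, 5, 1, 0, 0, 0, 0, 6, 7, 2), mode = "SE",
              env = "E1")
  calls <- callQTL(prof, 4)
  expect_equal(nrow(calls), 2)
  expect_equal(calls$pos, c(10, 90))   # plateau at 10/20 resolves leftmost
  expect_equal(callQTL(prof, 100)$pos, numeric(0))
  # regions separated by >= mergeWithin stay distinct, < merge into one
  p2 <- new("LODProfile", chrom = rep("1", 11), pos = seq(0, 100, 10),
            lod = c(5, 1, 5, 0, 0, 0, 0, 0, 0, 0, 0), mode = "SE", env = "E1")
  expect_equal(nrow(callQTL(p2, 4, mergeWithin = 30)), 1)
  expect_equal(nrow(callQTL(p2, 4, mergeWithin = 15)), 2)
})

test_that("joint QTL effect estimation recovers planted effects", {
  map <- simulateMap(nChrom = 2, totalLength = 200, nMarkers = 50, seed = 241)
  panel <- simulateNAMPanel(map, nPop = 2, linesPerPop = 150, seed = 242)
  Z <- genotypes(panel); X <- populationDesign(populationIds(panel))

  # exact recovery without noise
  eff <- matrix(c(1, -0.4, 0.8, -0.3), 2, 2)
  arch <- traitArchitecture(panel, nEnv = 2, nQTL = 2, qtlIndex = c(10, 35),
                            effects = eff, R0 = diag(0, 2), seed = 243,
                            popInterceptSD = 0)
  Y <- phenoValues(simulatePhenotypes(panel, arch, seed = 244))
  calls <- data.frame(chrom = chromosomes(map)[c(10, 35)],
                      pos = unname(positions(map)[c(10, 35)]), lod = c(9, 9))
  qf <- estimateQTLEffects(calls, Y, X, Z, map)
  expect_lt(max(abs(qf$effects - eff)), 1e-6)

  # two planted QTL with noise recovered within 20%
  arch2 <- traitArchitecture(panel, nEnv = 1, nQTL = 2, qtlIndex = c(10, 35),
                             effects = matrix(c(0.9, -0.8), 2, 1),
                             R0 = matrix(0.5), seed = 245, popInterceptSD = 0)
  Y2 <- phenoValues(simulatePhenotypes(panel, arch2, seed = 246))
  qf2 <- estimateQTLEffects(calls, Y2, X, Z, map)
  expect_lt(max(abs(qf2$effects[, 1] - c(0.9, -0.8)) / c(0.9, 0.8)), 0.2)

  # zero calls: prediction collapses to the overall mean
  qf0 <- estimateQTLEffects(calls[0, ], Y, X, Z, map)
  expect_equal(unname(predictQTL(qf0, Z[1:5, ], map, "E1")),
               rep(unname(qf0$mu[1]), 5))
})

test_that("iterative imputation beats column means under MCAR masking", {
  wins <- vapply(1:50, function(i) {
    mp <- simulateMap(nChrom = 2, totalLength = 120, nMarkers = 30,
                      seed = 700 + i)
    pn <- simulateNAMPanel(mp, nPop = 1, linesPerPop = 120, seed = 800 + i)
    ar <- traitArchitecture(pn, nEnv = 3, nQTL = 30, geneticCorr = 0.8,
                            residualCorr = 0.3, h2 = 0.7, seed = 900 + i)
    Y <- phenoValues(simulatePhenotypes(pn, ar, seed = 1000 + i))
    set.seed(1100 + i)
    mask <- matrix(runif(length(Y)) < 0.2, nrow(Y))
    mask[rowSums(mask) == ncol(Y), 1] <- FALSE
    Ym <- Y; Ym[mask] <- NA
    X <- populationDesign(populationIds(pn))
    imp <- imputePhenotypes(Ym, X)
    cm <- matrix(colMeans(Ym, na.rm = TRUE), nrow(Y), ncol(Y), byrow = TRUE)
    sqrt(mean((imp$Y[mask] - Y[mask])^2)) <
      sqrt(mean((cm[mask] - Y[mask])^2))
  }, logical(1))
  expect_gte(mean(wins), 0.95)
})

test_that("imputation handles the degenerate limits", {
  Y <- matrix(rnorm(20), 10, 2)
  X <- matrix(1, 10, 1)
  expect_identical(imputePhenotypes(Y, X)$Y, Y)
  # correlation-1 environments: the imputed cell equals its sibling up to the
  # mean shift
  Yc <- cbind(rnorm(50), 0)
  Yc[, 2] <- Yc[, 1] + 3
  Ym <- Yc; Ym[7, 2] <- NA
  imp <- imputePhenotypes(Ym, matrix(1, 50, 1))
  expect_equal(imp$Y[7, 2], Yc[7, 1] + 3, tolerance = 1e-3)
  expect_error(imputePhenotypes(rbind(c(NA, NA), c(1, 2)), matrix(1, 2, 1)),
               "missing all")
})
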