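# CV1/CV2 x WP/AP cross-validation engine: split/mask construction, training
# set assembly, accuracies, gains, paired tests, and the marker-density sweep.

#' CV1 split of one population
#'
#' Uniform random split without replacement; the training set holds
#' \code{floor(n * proportion)} lines and the remainder validates (their
#' records are masked in every environment).
#'
#' @param n number of lines in the population (>= 2).
#' @param proportion training proportion in (0, 1); study default 0.6.
#' @param seed integer seed; equal seeds give identical splits.
#' @return list with integer index vectors \code{train} and
#'   \code{validation}.
#' @export
splitCV1 <- function(n, proportion = 0.6, seed = 1) {
  stopifnot(proportion > 0, proportion < 1)
  if (n < 2) stop("population must have at least 2 lines")
  ntr <- floor(n * proportion)
  tr <- withSeed(seed, sort(sample.int(n, ntr)))
  list(train = tr, validation = setdiff(seq_len(n), tr))
}

#' CV2 random masking of phenotype records
#'
#' Masks each (line, environment) cell independently with probability
#' \code{rate}; lines left with no observed environment are dropped and
#' reported (expected fraction rate^m, e.g. 0.4^4 = 2.56\% for four
#' environments at rate 0.4).
#'
#' @param pheno a complete \linkS4class{PhenotypeTable}.
#' @param rate masking probability in [0, 1).
#' @param seed integer seed.
#' @return list with the masked \code{pheno} (dropped lines removed),
#'   \code{droppedLines}, and \code{maskAdded}, the full n x m logical mask
#'   drawn (before dropping).
#' @export
maskCV2 <- function(pheno, rate = 0.4, seed = 1) {
  stopifnot(is(pheno, "PhenotypeTable"), rate >= 0, rate < 1)
  n <- length(pheno@lineIds); m <- length(pheno@env)
  add <- withSeed(seed, matrix(runif(n * m) < rate, n, m))
  mask <- pheno@mask | add
  dropped <- rowSums(!mask) == 0
  vals <- pheno@values
  vals[mask] <- NA
  out <- new("PhenotypeTable",
             lineIds = pheno@lineIds[!dropped],
             popIds = pheno@popIds[!dropped],
             env = pheno@env,
             values = vals[!dropped, , drop = FALSE],
             mask = mask[!dropped, , drop = FALSE])
  list(pheno = out, droppedLines = pheno@lineIds[dropped], maskAdded = add)
}

#' Assemble a training data set for a CV scheme and scope
#'
#' Within-population (WP) training uses the test population's non-validation
#' lines (CV1) or its unmasked cells (CV2); across-population (AP) training
#' uses all lines of the other populations (CV1) or all populations' unmasked
#' cells including the test population (CV2).
#'
#' @param scope "WP" or "AP".
#' @param scheme "CV1" or "CV2".
#' @param panel the \linkS4class{NAMPanel}.
#' @param pheno the full (unmasked) \linkS4class{PhenotypeTable}.
#' @param testPop population id under validation.
#' @param split CV1 split of the test population from
#'   \code{\link{splitCV1}}.
#' @param masked CV2 masking from \code{\link{maskCV2}}.
#' @return list: \code{lineIdx} (panel row indices), \code{Y} (training
#'   values, NA where unobserved), \code{X} (population design), \code{pop}
#'   (population ids), \code{validationIdx} (panel row indices of validation
#'   lines).
#' @export
buildTraining <- function(scope = c("WP", "AP"), scheme = c("CV1", "CV2"),
                          panel, pheno, testPop, split = NULL, masked = NULL) {
  scope <- match.arg(scope); scheme <- match.arg(scheme)
  pops <- populationIds(panel)
  ids <- lineIds(panel)
  if (!testPop %in% pops) stop("unknown test population: ", testPop)
  popSel <- which(pops == testPop)
  Yfull <- pheno@values
  if (scheme == "CV1") {
    if (is.null(split)) stop("CV1 requires a split")
    valIdx <- popSel[split$validation]
    trIdx <- if (scope == "WP") popSel[split$train] else which(pops != testPop)
    Y <- Yfull[trIdx, , drop = FALSE]
  } else {
    if (is.null(masked)) stop("CV2 requires a masking")
    keep <- ids %in% masked$pheno@lineIds
    trIdx <- if (scope == "WP") which(keep & pops == testPop) else which(keep)
    row <- match(ids[trIdx], masked$pheno@lineIds)
    Y <- masked$pheno@values[row, , drop = FALSE]
    valIdx <- which(keep & pops == testPop)
  }
  if (length(trIdx) == 0) stop("empty training set")
  list(lineIdx = trIdx, Y = Y, X = populationDesign(pops[trIdx]),
       pop = pops[trIdx], validationIdx = valIdx)
}

#' Prediction accuracy
#'
#' Pearson correlation between predicted breeding values and the observed
#' phenotypes of the validation lines; NA (flagged and excluded from
#' averaging upstream) when either vector is constant.
#'
#' @param predicted,observed numeric vectors of equal length (>= 3).
#' @return correlation in [-1, 1], or NA.
#' @export
predictionAccuracy <- function(predicted, observed) {
  if (length(predicted) != length(observed)) stop("length mismatch")
  if (length(predicted) < 3) stop("need at least 3 paired values")
  if (sd(predicted) == 0 || sd(observed) == 0) return(NA_real_)
  cor(predicted, observed)
}

#' Relative gain in accuracy
#'
#' \eqn{(R_A - R_B) / R_B} between two models evaluated on identical
#' validation sets.
#'
#' @param rA,rB accuracies of models A and B.
#' @return the relative gain; NA with a warning when \code{rB} is 0.
#' @export
relativeGain <- function(rA, rB) {
  if (any(rB == 0)) {
    warning("relative gain undefined for zero reference accuracy")
    return(ifelse(rB == 0, NA_real_, (rA - rB) / rB))
  }
  (rA - rB) / rB
}

.modelName <- function(mod) {
  if (identical(mod$form, "ME"))
    paste0(mod$method, "-ME-", mod$structure %||% "UG-UR")
  else paste0(mod$method, "-SE")
}

.subsetMap <- function(map, idx) {
  new("GeneticMap", marker = map@marker[idx], chrom = map@chrom[idx],
      pos = map@pos[idx])
}

# one model's predictions for a set of validation lines, all environments
.fitPredict <- function(mod, scheme, train, Zall, mapK, cov0, envs, thresholds,
                        ctrl) {
  Ztr <- Zall[train$lineIdx, , drop = FALSE]
  Zval <- Zall[train$validationIdx, , drop = FALSE]
  m <- length(envs)
  preds <- matrix(NA_real_, nrow(Zval), m)
  est <- applyStructure(cov0, mod$structure %||% "UG-UR")
  if (mod$method == "GWP") {
    if (identical(mod$form, "SE")) {
      for (e in seq_len(m)) {
        oo <- !is.na(train$Y[, e])
        fit <- fitSERRBLUP(train$Y[oo, e],
                           train$X[oo, , drop = FALSE],
                           Ztr[oo, , drop = FALSE],
                           max(est@G0[e, e], 1e-8), max(est@R0[e, e], 1e-8),
                           env = envs[e])
        preds[, e] <- predictBV(fit, Zval, envs[e])
      }
    } else {
      fit <- if (anyNA(train$Y))
        fitMEUnbalanced(train$Y, train$X, Ztr, est@G0, est@R0, envs = envs)
      else
        fitMERRBLUP(train$Y, train$X, Ztr, est@G0, est@R0, envs = envs)
      for (e in seq_len(m)) preds[, e] <- predictBV(fit, Zval, envs[e])
    }
  } else {                                  # QP: CIM-based prediction
    alphaEnter <- ctrl$alphaEnter
    if (identical(mod$form, "SE")) {
      for (e in seq_len(m)) {
        oo <- !is.na(train$Y[, e])
        y <- train$Y[oo, e, drop = FALSE]
        colnames(y) <- envs[e]
        Xo <- train$X[oo, , drop = FALSE]
        Go <- Ztr[oo, , drop = FALSE]
        cof <- selectCofactors(y, Xo, Go, alphaEnter, mode = "SE")
        prof <- cimScan(y, Xo, Go, mapK, cof$indices, step = ctrl$step,
                        mode = "SE", excludeWindow = ctrl$excludeWindow)
        calls <- callQTL(prof, thresholds[[paste0("SE.", envs[e])]],
                         ctrl$mergeWithin)
        qfit <- estimateQTLEffects(calls, y, Xo, Go, mapK)
        preds[, e] <- predictQTL(qfit, Zval, mapK, envs[e])
      }
    } else {
      Yc <- train$Y
      if (anyNA(Yc))
        Yc <- imputePhenotypes(Yc, train$X, Sigma = est@G0 + est@R0)$Y
      colnames(Yc) <- envs
      cof <- selectCofactors(Yc, train$X, Ztr, alphaEnter, mode = "ME")
      prof <- cimScan(Yc, train$X, Ztr, mapK, cof$indices, step = ctrl$step,
                      mode = "ME", excludeWindow = ctrl$excludeWindow)
      calls <- callQTL(prof, thresholds[["ME.joint"]], ctrl$mergeWithin)
      qfit <- estimateQTLEffects(calls, Yc, train$X, Ztr, mapK)
      for (e in seq_len(m)) preds[, e] <- predictQTL(qfit, Zval, mapK, envs[e])
    }
  }
  preds
}

.pairComparisons <- function(results) {
  models <- unique(results$model)
  out <- NULL
  if (length(models) < 2) return(data.frame())
  # replicate-mean accuracies per model (over all populations/environments)
  for (i in seq_len(length(models) - 1)) for (j in (i + 1):length(models)) {
    a <- results[results$model == models[i], ]
    b <- results[results$model == models[j], ]
    am <- tapply(a$accuracy, a$replicate, mean, na.rm = TRUE)
    bm <- tapply(b$accuracy, b$replicate, mean, na.rm = TRUE)
    rep <- intersect(names(am), names(bm))
    d <- am[rep] - bm[rep]
    p <- if (sd(d) == 0) 1 else t.test(am[rep], bm[rep], paired = TRUE)$p.value
    out <- rbind(out, data.frame(
      modelA = models[i], modelB = models[j],
      meanA = mean(am[rep]), meanB = mean(bm[rep]),
      gain = relativeGain(mean(am[rep]), mean(bm[rep])),
      pValue = p, nPairs = length(rep)))
  }
  out
}

#' Run a cross-validation experiment
#'
#' Orchestrates replicated CV1 or CV2 cross-validation in WP or AP scope for
#' a set of models (genome-wide or QTL-based prediction, single- or
#' multi-environment, with a covariance structure tag for ME). Within a
#' replicate one split/mask is shared by all models so gains and paired
#' t-tests compare identical validation sets. Variance components are
#' estimated once per scope from the full phenotype records (per population
#' for WP, once on the combined panel for AP), as are permutation LOD
#' thresholds for QTL-based models; both can be supplied precomputed.
#'
#' @param panel a \linkS4class{NAMPanel}.
#' @param pheno the complete \linkS4class{PhenotypeTable}.
#' @param models list of model descriptors, each
#'   \code{list(method = "GWP"|"QP", form = "SE"|"ME", structure = tag)}.
#' @param scheme "CV1" or "CV2".
#' @param scope "WP" or "AP".
#' @param nRep replicate count (study default 100).
#' @param seed master seed; every split, mask and permutation derives from
#'   it.
#' @param trainProportion CV1 training fraction.
#' @param maskRate CV2 per-cell masking probability.
#' @param markerIdx marker subset to model (default: complete-LD-deduplicated
#'   set).
#' @param testPops populations to validate (default all).
#' @param nPerm permutations for QTL thresholds (study default 5000).
#' @param step,excludeWindow,mergeWithin CIM scan controls (cM).
#' @param covEstimates optional named list of precomputed
#'   \linkS4class{CovarianceEstimate}s ("AP" or one per population).
#' @param remlTol,remlMaxit REML convergence controls.
#' @return a \linkS4class{CVSummary}.
#' @export
runExperiment <- function(panel, pheno, models, scheme = c("CV1", "CV2"),
                          scope = c("WP", "AP"), nRep = 100, seed = 1,
                          trainProportion = 0.6, maskRate = 0.4,
                          markerIdx = NULL, testPops = NULL, nPerm = 5000,
                          step = 1, excludeWindow = 10, mergeWithin = 20,
                          covEstimates = NULL, remlTol = 1e-4,
                          remlMaxit = 100) {
  scheme <- match.arg(scheme); scope <- match.arg(scope)
  geno <- genotypes(panel)
  map <- panel@map
  if (is.null(markerIdx)) markerIdx <- dedupCompleteLD(geno, map)
  Zall <- geno[, markerIdx, drop = FALSE]
  mapK <- .subsetMap(map, markerIdx)
  pops <- populationIds(panel)
  envs <- pheno@env
  m <- length(envs)
  if (is.null(testPops)) testPops <- unique(pops)
  alphaEnter <- if (scope == "AP") 1e-4 else 0.01
  ctrl <- list(step = step, excludeWindow = excludeWindow,
               mergeWithin = mergeWithin, alphaEnter = alphaEnter)
  seeds <- splitSeed(seed, 3)
  # variance components from full records: per population (WP) / pooled (AP)
  if (is.null(covEstimates)) covEstimates <- list()
  getCov <- function(key, rows) {
    if (!is.null(covEstimates[[key]])) return(covEstimates[[key]])
    A <- computeGRM(Zall[rows, , drop = FALSE])
    est <- remlMultivariate(pheno@values[rows, , drop = FALSE],
                            populationDesign(pops[rows]), A,
                            tol = remlTol, maxit = remlMaxit)
    covEstimates[[key]] <<- est
    est
  }
  # permutation thresholds from full records for QTL-based models
  anyQP <- any(vapply(models, function(mo) mo$method == "QP", logical(1)))
  thSeeds <- splitSeed(seeds[2], length(testPops) * (m + 1))
  thresholds <- list()
  if (anyQP) {
    needSE <- any(vapply(models, function(mo)
      mo$method == "QP" && identical(mo$form, "SE"), logical(1)))
    needME <- any(vapply(models, function(mo)
      mo$method == "QP" && identical(mo$form, "ME"), logical(1)))
    for (ti in seq_along(testPops)) {
      tp <- testPops[ti]
      rows <- if (scope == "WP") which(pops == tp) else seq_along(pops)
      X <- populationDesign(pops[rows])
      th <- list()
      if (needSE) for (e in seq_len(m)) {
        th[[paste0("SE.", envs[e])]] <- permutationThreshold(
          pheno@values[rows, e, drop = FALSE], X,
          Zall[rows, , drop = FALSE], mapK, pops[rows], nPerm = nPerm,
          mode = "SE", cofactorRule = "reselect", alphaEnter = alphaEnter,
          step = step, seed = thSeeds[(ti - 1) * (m + 1) + e],
          excludeWindow = excludeWindow)$threshold
      }
      if (needME) {
        th[["ME.joint"]] <- permutationThreshold(
          pheno@values[rows, , drop = FALSE], X, Zall[rows, , drop = FALSE],
          mapK, pops[rows], nPerm = nPerm, mode = "ME",
          cofactorRule = "reselect", alphaEnter = alphaEnter, step = step,
          seed = thSeeds[ti * (m + 1)], excludeWindow = excludeWindow)$threshold
      }
      thresholds[[tp]] <- th
    }
  }
  repSeeds <- splitSeed(seeds[1], nRep)
  rows <- list(); ri <- 0
  for (r in seq_len(nRep)) {
    rs <- splitSeed(repSeeds[r], length(testPops) + 1)
    masked <- if (scheme == "CV2")
      maskCV2(pheno, maskRate, rs[length(testPops) + 1]) else NULL
    for (ti in seq_along(testPops)) {
      tp <- testPops[ti]
      split <- if (scheme == "CV1")
        splitCV1(sum(pops == tp), trainProportion, rs[ti]) else NULL
      train <- buildTraining(scope, scheme, panel, pheno, tp, split, masked)
      cov0 <- getCov(if (scope == "WP") tp else "AP",
                     if (scope == "WP") which(pops == tp) else seq_along(pops))
      valIdx <- train$validationIdx
      truth <- pheno@values[valIdx, , drop = FALSE]
      # which validation cells count: all (CV1) or the masked ones (CV2)
      valCells <- if (scheme == "CV1") {
        matrix(TRUE, length(valIdx), m)
      } else {
        masked$maskAdded[valIdx, , drop = FALSE]
      }
      for (mod in models) {
        preds <- tryCatch(
          .fitPredict(mod, scheme, train, Zall, mapK, cov0, envs,
                      thresholds[[tp]], ctrl),
          error = function(e) {
            warning(sprintf("replicate %d, %s failed: %s", r,
                            .modelName(mod), conditionMessage(e)))
            NULL
          })
        if (is.null(preds)) next
        for (e in seq_len(m)) {
          cc <- valCells[, e]
          acc <- if (sum(cc) >= 3)
            predictionAccuracy(preds[cc, e], truth[cc, e]) else NA_real_
          ri <- ri + 1
          rows[[ri]] <- data.frame(
            population = tp, environment = envs[e], model = .modelName(mod),
            replicate = r, accuracy = acc, nValidation = sum(cc))
        }
      }
    }
  }
  results <- do.call(rbind, rows)
  new("CVSummary", results = results,
      comparisons = .pairComparisons(results), nReplicates = nRep,
      config = list(scheme = scheme, scope = scope, seed = seed,
                    trainProportion = trainProportion, maskRate = maskRate,
                    nPerm = nPerm, models = vapply(models, .modelName,
                                                   character(1)),
                    covEstimates = covEstimates, thresholds = thresholds))
}

#' Marker-density sweep
#'
#' Re-runs genome-wide prediction under CV1 at a series of marker-thinning
#' spacings c (cM), with the split fixed per replicate across densities so
#' every density is applied to the same training and validation sets.
#'
#' @param panel,pheno data as in \code{\link{runExperiment}}.
#' @param cValues spacings in cM (study set: 1.6, 5, 10, 15, 20, 25, 30).
#' @param models GWP model descriptors (SE/ME).
#' @param scope "WP" or "AP".
#' @param nRep,seed,trainProportion as in \code{\link{runExperiment}}.
#' @param markerIdx marker subset before thinning (default deduplicated set).
#' @param testPops populations to validate.
#' @param covEstimates optional precomputed covariance estimates.
#' @param remlTol,remlMaxit REML controls.
#' @return a \linkS4class{CVSummary} whose results carry a \code{density}
#'   column.
#' @export
densitySweep <- function(panel, pheno, cValues,
                         models = list(list(method = "GWP", form = "SE"),
                                       list(method = "GWP", form = "ME")),
                         scope = "WP", nRep = 100, seed = 1,
                         trainProportion = 0.6, markerIdx = NULL,
                         testPops = NULL, covEstimates = NULL,
                         remlTol = 1e-4, remlMaxit = 100) {
  stopifnot(length(cValues) >= 1)
  geno <- genotypes(panel)
  map <- panel@map
  if (is.null(markerIdx)) markerIdx <- dedupCompleteLD(geno, map)
  mapD <- .subsetMap(map, markerIdx)
  pops <- populationIds(panel)
  envs <- pheno@env; m <- length(envs)
  if (is.null(testPops)) testPops <- unique(pops)
  if (is.null(covEstimates)) covEstimates <- list()
  Zfull <- geno[, markerIdx, drop = FALSE]
  getCov <- function(key, rows) {
    if (!is.null(covEstimates[[key]])) return(covEstimates[[key]])
    A <- computeGRM(Zfull[rows, , drop = FALSE])
    est <- remlMultivariate(pheno@values[rows, , drop = FALSE],
                            populationDesign(pops[rows]), A,
                            tol = remlTol, maxit = remlMaxit)
    covEstimates[[key]] <<- est
    est
  }
  # same split-seed derivation as runExperiment, so a sweep at full density
  # reproduces the plain CV1 experiment exactly
  seeds <- splitSeed(seed, 3)
  repSeeds <- splitSeed(seeds[1], nRep)
  thin <- lapply(cValues, function(cc) thinMarkers(mapD, cc))
  rows <- list(); ri <- 0
  for (r in seq_len(nRep)) {
    rs <- splitSeed(repSeeds[r], length(testPops) + 1)
    for (ti in seq_along(testPops)) {
      tp <- testPops[ti]
      split <- splitCV1(sum(pops == tp), trainProportion, rs[ti])
      train <- buildTraining(scope, "CV1", panel, pheno, tp, split)
      cov0 <- getCov(if (scope == "WP") tp else "AP",
                     if (scope == "WP") which(pops == tp) else seq_along(pops))
      truth <- pheno@values[train$validationIdx, , drop = FALSE]
      for (ci in seq_along(cValues)) {
        Zc <- Zfull[, thin[[ci]], drop = FALSE]
        mapC <- .subsetMap(mapD, thin[[ci]])
        for (mod in models) {
          preds <- .fitPredict(mod, "CV1", train, Zc, mapC, cov0, envs,
                               NULL, list())
          for (e in seq_len(m)) {
            ri <- ri + 1
            rows[[ri]] <- data.frame(
              population = tp, environment = envs[e],
              model = paste0(.modelName(mod), "@c", cValues[ci]),
              density = cValues[ci], replicate = r,
              accuracy = predictionAccuracy(preds[, e], truth[, e]),
              nValidation = nrow(preds))
          }
        }
      }
    }
  }
  results <- do.call(rbind, rows)
  new("CVSummary", results = results,
      comparisons = .pairComparisons(results), nReplicates = nRep,
      config = list(scheme = "CV1", scope = scope, seed = seed,
                    cValues = cValues, covEstimates = covEstimates))
}
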