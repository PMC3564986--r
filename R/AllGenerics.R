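#' Accessors for namGP classes
#'
#' Small accessor family: marker names, positions and chromosomes of a
#' \linkS4class{GeneticMap}; stacked genotypes, line and population ids of a
#' \linkS4class{NAMPanel}; values and mask of a \linkS4class{PhenotypeTable}.
#'
#' @param x an object.
#' @return the requested component.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("markerNames", function(x) standardGeneric("markerNames"))
#' @rdname accessors
#' @export
setGeneric("positions", function(x) standardGeneric("positions"))
#' @rdname accessors
#' @export
setGeneric("chromosomes", function(x) standardGeneric("chromosomes"))
#' @rdname accessors
#' @export
setGeneric("genotypes", function(x) standardGeneric("genotypes"))
#' @rdname accessors
#' @export
setGeneric("lineIds", function(x) standardGeneric("lineIds"))
#' @rdname accessors
#' @export
setGeneric("populationIds", function(x) standardGeneric("populationIds"))
#' @rdname accessors
#' @export
setGeneric("phenoValues", function(x) standardGeneric("phenoValues"))
#' @rdname accessors
#' @export
setGeneric("missingMask", function(x) standardGeneric("missingMask"))
#' @rdname accessors
#' @export
setGeneric("environments", function(x) standardGeneric("environments"))
#' @rdname accessors
#' @export
setGeneric("geneticCovariance", function(x) standardGeneric("geneticCovariance"))
#' @rdname accessors
#' @export
setGeneric("residualCovariance", function(x) standardGeneric("residualCovariance"))
#' @rdname accessors
#' @export
setGeneric("markerEffects", function(x) standardGeneric("markerEffects"))

#' @rdname accessors
#' @export
setMethod("markerNames", "GeneticMap", function(x) x@marker)
#' @rdname accessors
#' @export
setMethod("positions", "GeneticMap", function(x) setNames(x@pos, x@marker))
#' @rdname accessors
#' @export
setMethod("chromosomes", "GeneticMap", function(x) setNames(x@chrom, x@marker))

#' @rdname accessors
#' @export
setMethod("genotypes", "RILPopulation", function(x) {
  g <- x@geno
  rownames(g) <- x@lineIds
  g
})
#' @rdname accessors
#' @export
setMethod("lineIds", "RILPopulation", function(x) x@lineIds)

#' @rdname accessors
#' @export
setMethod("genotypes", "NAMPanel", function(x) {
  do.call(rbind, lapply(x@populations, genotypes))
})
#' @rdname accessors
#' @export
setMethod("lineIds", "NAMPanel", function(x)
  unlist(lapply(x@populations, slot, "lineIds"), use.names = FALSE))
#' @rdname accessors
#' @export
setMethod("populationIds", "NAMPanel", function(x)
  unlist(lapply(x@populations, function(p) rep(p@popId, length(p@lineIds))),
         use.names = FALSE))

#' @rdname accessors
#' @export
setMethod("phenoValues", "PhenotypeTable", function(x) {
  v <- x@values
  dimnames(v) <- list(x@lineIds, x@env)
  v
})
#' @rdname accessors
#' @export
setMethod("missingMask", "PhenotypeTable", function(x) x@mask)
#' @rdname accessors
#' @export
setMethod("environments", "PhenotypeTable", function(x) x@env)
#' @rdname accessors
#' @export
setMethod("lineIds", "PhenotypeTable", function(x) x@lineIds)
#' @rdname accessors
#' @export
setMethod("populationIds", "PhenotypeTable", function(x) x@popIds)

#' @rdname accessors
#' @export
setMethod("geneticCovariance", "CovarianceEstimate", function(x) x@G0)
#' @rdname accessors
#' @export
setMethod("residualCovariance", "CovarianceEstimate", function(x) x@R0)
#' @rdname accessors
#' @export
setMethod("markerEffects", "MMEFit", function(x) {
  a <- x@alpha
  dimnames(a) <- list(x@markers, x@envs)
  a
})

setMethod("show", "GeneticMap", function(object) {
  ch <- unique(object@chrom)
  spans <- vapply(ch, function(cc) {
    p <- object@pos[object@chrom == cc]
    max(p) - min(p)
  }, numeric(1))
  cat("GeneticMap:", length(object@marker), "markers on", length(ch),
      "chromosomes,", round(sum(spans), 1), "cM total\n")
})

setMethod("show", "NAMPanel", function(object) {
  n <- vapply(object@populations, function(p) length(p@lineIds), integer(1))
  cat("NAMPanel:", length(object@populations), "RIL populations,",
      sum(n), "lines,", length(object@map@marker), "markers\n")
})

setMethod("show", "PhenotypeTable", function(object) {
  cat("PhenotypeTable:", length(object@lineIds), "lines x",
      length(object@env), "environments;",
      sum(object@mask), "missing cells\n")
})

setMethod("show", "CovarianceEstimate", function(object) {
  cat("CovarianceEstimate [", object@structure, "] m =", nrow(object@G0),
      "\n  restricted logLik:", format(object@loglik),
      " iterations:", object@iterations,
      " converged:", object@converged, "\n")
  cat("  genetic variances:", paste(signif(diag(object@G0), 4), collapse = ", "), "\n")
  cat("  residual variances:", paste(signif(diag(object@R0), 4), collapse = ", "), "\n")
})

setMethod("show", "MMEFit", function(object) {
  cat("MMEFit:", length(object@markers), "predictors x",
      length(object@envs), "environments [", object@structure, "]\n")
  cat("  overall means:", paste(signif(object@mu, 4), collapse = ", "), "\n")
})

setMethod("show", "CVSummary", function(object) {
  cat("CVSummary:", object@nReplicates, "replicates,",
      length(unique(object@results$model)), "models\n")
  agg <- stats::aggregate(accuracy ~ model, data = object@results, FUN = mean,
                          na.rm = TRUE)
  for (i in seq_len(nrow(agg)))
    cat(sprintf("  %-28s mean accuracy %.3f\n", agg$model[i], agg$accuracy[i]))
})
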