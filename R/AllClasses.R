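#' @import methods
#' @importFrom stats cor cov optimize pf pt quantile rnorm runif sd setNames t.test var
#' @importFrom utils read.table write.table head
NULL

#' GeneticMap: ordered marker positions in centimorgan
#'
#' Container for a sex-averaged genetic map: one row per marker with its
#' chromosome and cM position. Positions are strictly increasing within each
#' chromosome and marker names are unique panel-wide. The map is the shared
#' coordinate system for RIL simulation, genome scans and marker thinning.
#'
#' @slot marker character vector of unique marker names (map order).
#' @slot chrom character vector of chromosome identifiers, one per marker.
#' @slot pos numeric vector of cM positions, non-negative, strictly
#'   increasing within chromosome.
#' @exportClass GeneticMap
setClass("GeneticMap",
  representation(marker = "character", chrom = "character", pos = "numeric"))

setValidity("GeneticMap", function(object) {
  if (length(object@marker) != length(object@chrom) ||
      length(object@marker) != length(object@pos))
    return("marker, chrom and pos must have equal length")
  if (anyDuplicated(object@marker))
    return("marker names must be unique panel-wide")
  if (any(object@pos < 0)) return("positions must be non-negative")
  for (ch in unique(object@chrom)) {
    p <- object@pos[object@chrom == ch]
    if (any(diff(p) <= 0))
      return(sprintf("positions must be strictly increasing on chromosome %s", ch))
  }
  TRUE
})

#' RILPopulation: one biparental RIL population
#'
#' Genotypes are coded +1 for the common-parent homozygote, -1 for the
#' diverse-parent homozygote and 0 otherwise; the simulator emits pure
#' +/-1 genotypes (fully inbred lines) but 0 is accepted downstream.
#'
#' @slot popId single population identifier.
#' @slot parents length-2 character: common parent, diverse parent.
#' @slot lineIds character vector of line identifiers.
#' @slot geno numeric matrix (lines x markers) with entries in {-1, 0, +1}.
#' @exportClass RILPopulation
setClass("RILPopulation",
  representation(popId = "character", parents = "character",
                 lineIds = "character", geno = "matrix"))

setValidity("RILPopulation", function(object) {
  if (length(object@parents) != 2) return("parents must have length 2")
  if (nrow(object@geno) != length(object@lineIds))
    return("geno row count must equal number of line ids")
  if (!all(object@geno %in% c(-1, 0, 1)))
    return("genotype codes must be in {-1, 0, +1}")
  TRUE
})

#' NAMPanel: a set of RIL populations sharing one genetic map
#'
#' All populations are genotyped on the same marker set in map order and share
#' a common parent, mirroring a nested association mapping design.
#'
#' @slot map a \linkS4class{GeneticMap}.
#' @slot populations list of \linkS4class{RILPopulation}.
#' @exportClass NAMPanel
setClass("NAMPanel",
  representation(map = "GeneticMap", populations = "list"))

setValidity("NAMPanel", function(object) {
  k <- length(object@map@marker)
  for (p in object@populations) {
    if (!is(p, "RILPopulation")) return("populations must be RILPopulation objects")
    if (ncol(p@geno) != k)
      return("every population must be genotyped on the full map marker set")
  }
  ids <- unlist(lapply(object@populations, slot, "lineIds"))
  if (anyDuplicated(ids)) return("line ids must be unique across populations")
  TRUE
})

#' TraitArchitecture: QTL positions, effects and fixed structure
#'
#' The generative ground truth for multi-environment phenotypes: additive QTL
#' effects per environment, per-population intercepts, environment means and
#' the target across-environment genetic (G0) and residual (R0) covariances.
#'
#' @slot qtlIndex integer indices into the map's markers where QTL sit.
#' @slot effects numeric matrix (nQTL x m) of additive effects per environment.
#' @slot intercepts numeric matrix (nPop x m) of population-by-environment
#'   deviations.
#' @slot muEnv numeric length-m environment means.
#' @slot G0 target m x m genetic covariance used for generation.
#' @slot R0 target m x m residual covariance used for generation.
#' @slot envNames character length-m environment labels.
#' @exportClass TraitArchitecture
setClass("TraitArchitecture",
  representation(qtlIndex = "integer", effects = "matrix",
                 intercepts = "matrix", muEnv = "numeric",
                 G0 = "matrix", R0 = "matrix", envNames = "character"))

setValidity("TraitArchitecture", function(object) {
  m <- length(object@muEnv)
  if (nrow(object@effects) != length(object@qtlIndex))
    return("effects must have one row per QTL")
  if (length(object@qtlIndex) > 0 && ncol(object@effects) != m)
    return("effects must have one column per environment")
  if (!all(dim(object@G0) == c(m, m)) || !all(dim(object@R0) == c(m, m)))
    return("G0 and R0 must be m x m")
  TRUE
})

#' PhenotypeTable: line-by-environment trait values with missingness
#'
#' Values carry NA exactly where the mask is TRUE. Environment order is the
#' indexing convention for G0/R0 throughout the package.
#'
#' @slot lineIds character line identifiers (row order).
#' @slot popIds character population identifier per line.
#' @slot env character environment labels (column order).
#' @slot values numeric matrix (n x m), NA where masked.
#' @slot mask logical matrix (n x m), TRUE = missing.
#' @exportClass PhenotypeTable
setClass("PhenotypeTable",
  representation(lineIds = "character", popIds = "character",
                 env = "character", values = "matrix", mask = "matrix"))

setValidity("PhenotypeTable", function(object) {
  if (nrow(object@values) != length(object@lineIds) ||
      length(object@popIds) != length(object@lineIds))
    return("values rows, lineIds and popIds must agree")
  if (ncol(object@values) != length(object@env))
    return("values columns must match environment labels")
  if (!identical(dim(object@values), dim(object@mask)))
    return("values and mask must have identical dimensions")
  if (!identical(unname(is.na(object@values)), unname(object@mask)))
    return("mask must be TRUE exactly where values are NA")
  TRUE
})

#' CovarianceEstimate: estimated G0 and R0 with fit metadata
#'
#' @slot G0 m x m genetic covariance (diagonal sigma_ii^2, off-diagonal
#'   rho_ij sigma_ii sigma_jj).
#' @slot R0 m x m residual covariance (diagonal e_ii^2, off-diagonal
#'   r_ij e_ii e_jj).
#' @slot structure one of "SG-SR", "SG-UR", "UG-SR", "UG-UR".
#' @slot loglik converged restricted log-likelihood.
#' @slot iterations EM iteration count.
#' @slot converged logical convergence flag.
#' @exportClass CovarianceEstimate
setClass("CovarianceEstimate",
  representation(G0 = "matrix", R0 = "matrix", structure = "character",
                 loglik = "numeric", iterations = "numeric",
                 converged = "logical"))

setValidity("CovarianceEstimate", function(object) {
  if (!isTRUE(all.equal(object@G0, t(object@G0), tolerance = 1e-8)) ||
      !isTRUE(all.equal(object@R0, t(object@R0), tolerance = 1e-8)))
    return("G0 and R0 must be symmetric")
  if (any(diag(object@G0) < 0) || any(diag(object@R0) < 0))
    return("variances must be non-negative")
  if (!object@structure %in% c("SG-SR", "SG-UR", "UG-SR", "UG-UR"))
    return("unknown covariance structure tag")
  TRUE
})

#' MMEFit: solved mixed-model (or QTL-regression) equations
#'
#' Fixed effects are parameterised with a leading overall mean and sum-to-zero
#' population deviations; \code{mu} is the environment-specific overall mean
#' used by the prediction equation. \code{alpha} holds environment-specific
#' effects of the fitted predictor columns (all markers for genome-wide
#' prediction, expected QTL genotypes for QTL-based prediction).
#'
#' @slot beta numeric matrix (q x m) of fixed-effect solutions.
#' @slot mu numeric length-m environment-specific overall means.
#' @slot alpha numeric matrix (k x m) of predictor effects per environment.
#' @slot G0,R0 covariance matrices used in the solve.
#' @slot structure covariance structure tag.
#' @slot denom the marker-variance denominator 2*sum p(1-p).
#' @slot markers character names of the predictor columns.
#' @slot envs character environment labels.
#' @slot diagnostics list of solver notes (singularity flags etc.).
#' @exportClass MMEFit
setClass("MMEFit",
  representation(beta = "matrix", mu = "numeric", alpha = "matrix",
                 G0 = "matrix", R0 = "matrix", structure = "character",
                 denom = "numeric", markers = "character", envs = "character",
                 diagnostics = "list"))

#' LODProfile: a genome-scan LOD curve
#'
#' @slot chrom chromosome per scan position.
#' @slot pos cM position per scan position (includes all marker positions).
#' @slot lod non-negative LOD score per position.
#' @slot mode "SE" or "ME".
#' @slot env environment label (SE) or "joint" (ME).
#' @exportClass LODProfile
setClass("LODProfile",
  representation(chrom = "character", pos = "numeric", lod = "numeric",
                 mode = "character", env = "character"))

setValidity("LODProfile", function(object) {
  if (any(object@lod < -1e-8)) return("LOD scores must be non-negative")
  TRUE
})

#' CVSummary: replicate-level cross-validation results and comparisons
#'
#' @slot results long data.frame: population, environment, model, replicate,
#'   accuracy (NA when the correlation was undefined).
#' @slot comparisons data.frame of pairwise model contrasts: mean accuracies,
#'   relative gain and paired t-test p-value on identical validation sets.
#' @slot nReplicates replicate count.
#' @slot config the experiment configuration (seeds included).
#' @exportClass CVSummary
setClass("CVSummary",
  representation(results = "data.frame", comparisons = "data.frame",
                 nReplicates = "numeric", config = "list"))
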