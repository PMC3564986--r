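# Internal numerical and randomness helpers.

# Derive independent sub-seeds from one master seed. All exported stochastic
# operations take a single integer seed and draw their sub-streams through
# this rule, so whole experiments replay bit-for-bit from one number.
splitSeed <- function(seed, n) {
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  sample.int(.Machine$integer.max - 1L, n)
}

withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  expr
}

# Haldane recombination fraction for a distance d in cM.
haldaneR <- function(d) (1 - exp(-2 * d / 100)) / 2

# Haldane-Waddington switch probability between adjacent loci of a selfed RIL:
# R = 2r / (1 + 2r).
rilSwitchProb <- function(d) {
  r <- haldaneR(d)
  2 * r / (1 + 2 * r)
}

# Project a symmetric matrix to the nearest PSD matrix by eigenvalue clipping.
projectPSD <- function(S, floor = 0) {
  S <- (S + t(S)) / 2
  e <- eigen(S, symmetric = TRUE)
  if (all(e$values >= floor)) return(S)
  v <- pmax(e$values, floor)
  S2 <- e$vectors %*% (v * t(e$vectors))
  (S2 + t(S2)) / 2
}

isPSD <- function(S, tol = 1e-8) {
  if (!isTRUE(all.equal(S, t(S), tolerance = 1e-6))) return(FALSE)
  ev <- eigen((S + t(S)) / 2, symmetric = TRUE, only.values = TRUE)$values
  all(ev >= -tol * max(abs(ev), 1))
}

#' Population-structure fixed-effect design
#'
#' Fixed-effect incidence for n lines from p populations: a leading ones
#' column plus sum-to-zero population deviation contrasts, so the first
#' coefficient is the overall mean required by the prediction equation (the
#' ones column and full population indicators would be collinear). With a
#' single population the design is the ones column alone.
#'
#' @param popIds population identifier per line.
#' @return numeric design matrix (n x p) with a leading \code{"mu"} column.
#' @export
populationDesign <- function(popIds) {
  popIds <- as.character(popIds)
  pops <- unique(popIds)
  n <- length(popIds)
  if (length(pops) == 1L) {
    X <- matrix(1, n, 1, dimnames = list(NULL, "mu"))
    return(X)
  }
  f <- factor(popIds, levels = pops)
  C <- stats::contr.sum(length(pops))
  X <- cbind(1, C[as.integer(f), , drop = FALSE])
  colnames(X) <- c("mu", paste0("pop_", pops[-length(pops)]))
  X
}

# Solve a symmetric linear system, falling back to a minimum-norm
# pseudo-inverse solution when the system is singular; the fallback is
# reported through the returned "singular" attribute.
solveMaybeSingular <- function(C, rhs) {
  sol <- tryCatch(list(x = solve(C, rhs), singular = FALSE),
                  error = function(e) NULL)
  if (is.null(sol))
    sol <- list(x = MASS::ginv(C) %*% rhs, singular = TRUE)
  sol
}
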