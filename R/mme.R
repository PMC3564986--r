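# Henderson mixed-model equation solvers for single- and multi-environment
# ridge-regression BLUP. The line-level genetic covariance factor G0 is
# converted to the marker-effect prior by the denominator 2*sum p(1-p), so
# G = G0 (x) A and alpha ~ N(0, (G0/denom) (x) I_k) are internally consistent.

.invertClipped <- function(S, events, what) {
  e <- eigen((S + t(S)) / 2, symmetric = TRUE)
  tolv <- 1e-10 * max(abs(e$values))
  if (any(e$values <= tolv)) {
    events <- c(events, sprintf("near-singular %s regularised by eigenvalue clipping", what))
    vals <- pmax(e$values, tolv)
  } else vals <- e$values
  list(inv = e$vectors %*% ((1 / vals) * t(e$vectors)), events = events)
}

#' Single-environment RR-BLUP via Henderson's equations
#'
#' Solves the univariate mixed model y = X beta + Z alpha + e with
#' alpha ~ N(0, I sigma_g^2 / (2 sum p(1-p))), i.e. ridge regression with
#' penalty lambda = sigma_e^2 / sigma_alpha^2. Singular systems fall back to
#' a minimum-norm solution and are flagged in the diagnostics.
#'
#' @param y phenotype vector (no missing entries).
#' @param X fixed-effect incidence (leading ones column; see
#'   \code{\link{populationDesign}}).
#' @param Z marker matrix (n x k).
#' @param sigmaG2 line-level genetic variance (> 0 after flooring).
#' @param sigmaE2 residual variance (> 0).
#' @param freqs marker allele frequencies for the denominator (defaults to
#'   \code{alleleFreq(Z)}).
#' @param env environment label carried into the fit.
#' @return an \linkS4class{MMEFit} with one environment.
#' @export
fitSERRBLUP <- function(y, X, Z, sigmaG2, sigmaE2, freqs = alleleFreq(Z),
                        env = "E1") {
  stopifnot(!anyNA(y), sigmaG2 > 0, sigmaE2 > 0)
  denom <- 2 * sum(freqs * (1 - freqs))
  lambda <- sigmaE2 / (sigmaG2 / denom)
  q <- ncol(X); k <- ncol(Z)
  C <- rbind(cbind(crossprod(X), crossprod(X, Z)),
             cbind(crossprod(Z, X), crossprod(Z) + diag(lambda, k)))
  rhs <- c(crossprod(X, y), crossprod(Z, y))
  sol <- solveMaybeSingular(C, rhs)
  beta <- matrix(sol$x[seq_len(q)], q, 1)
  alpha <- matrix(sol$x[q + seq_len(k)], k, 1)
  new("MMEFit", beta = beta, mu = setNames(beta[1, 1], env), alpha = alpha,
      G0 = matrix(sigmaG2, 1, 1), R0 = matrix(sigmaE2, 1, 1),
      structure = "UG-UR", denom = denom,
      markers = colnames(Z) %||% paste0("M", seq_len(k)), envs = env,
      diagnostics = list(singular = sol$singular, lambda = lambda))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Multi-environment RR-BLUP via stacked Henderson equations (balanced)
#'
#' Solves the stacked model for complete (CV1-style) records: environment
#' blocks share X and Z, marker effects have prior N(0, (G0/denom) (x) I_k)
#' and residuals have covariance R0 (x) I_n. Diagonal G0 and R0 decouple the
#' system into the per-environment single-environment fits.
#'
#' @param Y n x m phenotype matrix with no missing cells.
#' @param X fixed-effect incidence (n x q).
#' @param Z marker matrix (n x k).
#' @param G0,R0 m x m line-level genetic and residual covariance (PSD with
#'   positive diagonals).
#' @param freqs marker allele frequencies for the denominator.
#' @param envs environment labels (defaults to Y's column names).
#' @return an \linkS4class{MMEFit}.
#' @export
fitMERRBLUP <- function(Y, X, Z, G0, R0, freqs = alleleFreq(Z),
                        envs = colnames(Y)) {
  Y <- as.matrix(Y)
  stopifnot(!anyNA(Y))
  m <- ncol(Y)
  if (is.null(envs)) envs <- paste0("E", seq_len(m))
  if (!isPSD(G0) || !isPSD(R0))
    stop("G0 and R0 must be positive semi-definite")
  if (any(diag(G0) <= 0) || any(diag(R0) <= 0))
    stop("G0 and R0 must have positive diagonals")
  events <- character(0)
  denom <- 2 * sum(freqs * (1 - freqs))
  G0m <- G0 / denom
  iR <- .invertClipped(R0, events, "R0"); R0inv <- iR$inv; events <- iR$events
  iG <- .invertClipped(G0m, events, "G0"); G0minv <- iG$inv; events <- iG$events
  q <- ncol(X); k <- ncol(Z); b <- q + k
  XtX <- crossprod(X); XtZ <- crossprod(X, Z); ZtZ <- crossprod(Z)
  B <- rbind(cbind(XtX, XtZ), cbind(t(XtZ), ZtZ))
  C <- kronecker(R0inv, B)
  for (e in seq_len(m)) for (f in seq_len(m)) {
    ia <- (e - 1) * b + q + seq_len(k)
    ja <- (f - 1) * b + q + seq_len(k)
    if (G0minv[e, f] != 0)
      C[cbind(ia, ja)] <- C[cbind(ia, ja)] + G0minv[e, f]
  }
  XtY <- crossprod(X, Y); ZtY <- crossprod(Z, Y)
  rhs <- numeric(m * b)
  for (e in seq_len(m)) {
    acc <- numeric(b)
    for (f in seq_len(m))
      acc <- acc + R0inv[e, f] * c(XtY[, f], ZtY[, f])
    rhs[(e - 1) * b + seq_len(b)] <- acc
  }
  sol <- solveMaybeSingular(C, rhs)
  if (sol$singular) events <- c(events, "singular Henderson system: minimum-norm solution")
  theta <- matrix(sol$x, b, m)
  beta <- theta[seq_len(q), , drop = FALSE]
  alpha <- theta[q + seq_len(k), , drop = FALSE]
  new("MMEFit", beta = beta, mu = setNames(beta[1, ], envs), alpha = alpha,
      G0 = G0, R0 = R0, structure = "UG-UR", denom = denom,
      markers = colnames(Z) %||% paste0("M", seq_len(k)), envs = envs,
      diagnostics = list(events = events, singular = sol$singular))
}

#' Observation-level covariance for unbalanced records
#'
#' For observation rows (line l, environment i) the genetic covariance entry
#' is \eqn{Z_l Z_q^T \sigma_{ij}^2 / (2\sum_h p_h(1-p_h))} and the residual
#' entry is \eqn{e_{ij}^2} when the two rows come from the same line and zero
#' otherwise.
#'
#' @param lineIdx integer line index per observation row.
#' @param envIdx integer environment index per observation row.
#' @param Z marker matrix with one row per line (indexed by \code{lineIdx}).
#' @param G0,R0 m x m covariance matrices.
#' @param freqs marker allele frequencies (length = ncol(Z)).
#' @return list with dense \code{G} and \code{R} (N x N), the \code{denom},
#'   and the row metadata.
#' @export
buildUnbalancedCovariance <- function(lineIdx, envIdx, Z, G0, R0,
                                      freqs = alleleFreq(Z)) {
  stopifnot(length(lineIdx) == length(envIdx), ncol(Z) == length(freqs))
  denom <- 2 * sum(freqs * (1 - freqs))
  A <- tcrossprod(Z) / denom
  N <- length(lineIdx)
  Gm <- A[lineIdx, lineIdx] * matrix(G0[cbind(rep(envIdx, times = N),
                                              rep(envIdx, each = N))], N, N)
  Rm <- matrix(R0[cbind(rep(envIdx, times = N), rep(envIdx, each = N))], N, N) *
    outer(lineIdx, lineIdx, "==")
  list(G = Gm, R = Rm, denom = denom, lineIdx = lineIdx, envIdx = envIdx)
}

#' Multi-environment RR-BLUP for unbalanced (CV2-style) records
#'
#' Generalised-least-squares/BLUP solve on the observed cells using the
#' observation-level covariance, followed by back-transformation of the
#' line-level BLUP to environment-specific marker effects,
#' \eqn{\hat\alpha = (G0/denom (x) I_k) Z_s^T V^{-1} (y - X\hat\beta)}.
#' With no missing cells the result equals \code{\link{fitMERRBLUP}}.
#'
#' @param Y n x m phenotype matrix with NA for missing cells; lines missing
#'   every environment must be dropped beforehand.
#' @param X fixed-effect incidence (n x q, one row per line).
#' @param Z marker matrix (n x k, one row per line).
#' @param G0,R0 m x m covariance matrices.
#' @param freqs marker allele frequencies.
#' @param envs environment labels.
#' @return an \linkS4class{MMEFit}.
#' @export
fitMEUnbalanced <- function(Y, X, Z, G0, R0, freqs = alleleFreq(Z),
                            envs = colnames(Y)) {
  Y <- as.matrix(Y)
  m <- ncol(Y)
  if (is.null(envs)) envs <- paste0("E", seq_len(m))
  if (!isPSD(G0) || !isPSD(R0))
    stop("G0 and R0 must be positive semi-definite")
  if (any(rowSums(!is.na(Y)) == 0))
    stop("lines missing all environments must be excluded upstream")
  if (any(colSums(!is.na(Y)) == 0))
    stop("every environment needs at least one observation")
  obs <- which(!is.na(Y), arr.ind = TRUE)
  li <- obs[, 1]; ei <- obs[, 2]
  yv <- Y[obs]
  cov <- buildUnbalancedCovariance(li, ei, Z, G0, R0, freqs)
  V <- cov$G + cov$R
  N <- length(yv); q <- ncol(X); k <- ncol(Z)
  K <- tryCatch(chol(V),
                error = function(e) chol(V + diag(1e-8 * mean(diag(V)), N)))
  solveV <- function(x) backsolve(K, forwardsolve(t(K), x))
  D <- matrix(0, N, m * q)
  for (e in seq_len(m)) {
    sel <- ei == e
    D[sel, (e - 1) * q + seq_len(q)] <- X[li[sel], , drop = FALSE]
  }
  WD <- solveV(D)
  S <- crossprod(D, WD)
  sol <- solveMaybeSingular(S, crossprod(WD, yv))
  betaV <- sol$x
  r <- yv - D %*% betaV
  w <- solveV(r)
  G0m <- G0 / cov$denom
  # s_j = Z_j' w_j accumulated per environment, then mixed through G0m
  Smat <- matrix(0, k, m)
  for (e in seq_len(m)) {
    sel <- ei == e
    if (any(sel))
      Smat[, e] <- crossprod(Z[li[sel], , drop = FALSE], w[sel])
  }
  alpha <- Smat %*% t(G0m)
  beta <- matrix(betaV, q, m)
  new("MMEFit", beta = beta, mu = setNames(beta[1, ], envs), alpha = alpha,
      G0 = G0, R0 = R0, structure = "UG-UR", denom = cov$denom,
      markers = colnames(Z) %||% paste0("M", seq_len(k)), envs = envs,
      diagnostics = list(singular = sol$singular, nObs = N))
}

#' Predict breeding values in a validation set
#'
#' The prediction equation \eqn{\hat y_i = \hat\mu_e + \sum_j z_{ij}
#' \hat\alpha_{je}}: environment-specific overall mean plus marker (or QTL)
#' effects. Population deviations are deliberately excluded.
#'
#' @param fit an \linkS4class{MMEFit}.
#' @param Zval validation genotype matrix in the training marker order.
#' @param environment environment label present in the fit.
#' @return numeric vector of predicted breeding values.
#' @export
predictBV <- function(fit, Zval, environment) {
  stopifnot(is(fit, "MMEFit"))
  e <- match(environment, fit@envs)
  if (is.na(e)) stop("environment label not in fit: ", environment)
  if (ncol(Zval) != nrow(fit@alpha))
    stop("validation genotypes do not match the training marker set")
  drop(fit@mu[e] + Zval %*% fit@alpha[, e])
}
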