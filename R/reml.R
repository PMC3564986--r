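# Variance-component estimation for the line-level (GBLUP-equivalent) model
#
#   vec(Y) = (I_m (x) X) vec(B) + u + e,  u ~ N(0, G0 (x) A),  e ~ N(0, R0 (x) I)
#
# estimated by restricted maximum likelihood. The balanced path rotates by the
# eigenvectors of A and simultaneously diagonalises (G0, R0) each EM
# iteration, which reduces every E-step to elementwise work on an n x m grid;
# the unbalanced path evaluates the observed-cell likelihood with dense
# matrices. Both are EM-REML, so the restricted log-likelihood is
# non-decreasing across iterations.

# restricted log-likelihood of (sg2, se2) on the rotated univariate model
.remlLogLikUni <- function(ys, Xs, d, sg2, se2) {
  v <- sg2 * d + se2
  w <- 1 / v
  S <- crossprod(Xs, Xs * w)
  b <- solve(S, crossprod(Xs * w, ys))
  r <- ys - Xs %*% b
  n <- length(ys); q <- ncol(Xs)
  -0.5 * (sum(log(v)) + sum(w * r^2) + determinant(S)$modulus[1] +
          (n - q) * log(2 * pi))
}

#' Univariate REML for one environment
#'
#' Estimates genetic and residual variance for y = X beta + u + e with
#' var(u) = A sigma_g^2, via the eigendecomposition of A and Brent search on
#' the profiled restricted likelihood over the variance ratio. Deterministic;
#' variances are floored at 1e-8 times the phenotypic variance.
#'
#' Note the scale convention: the genomic relationship matrix of fully
#' homozygous +/-1-coded lines has a constant diagonal k/(2 sum p(1-p)),
#' about 2, so the line-level genetic variance is diag(A) * sigma_g^2; the
#' reported heritability uses this conversion,
#' h2 = mean(diag(A)) sigma_g^2 / (mean(diag(A)) sigma_g^2 + sigma_e^2).
#'
#' @param y phenotype vector without missing entries.
#' @param X fixed-effect incidence matrix (see \code{populationDesign}).
#' @param A relationship matrix for the included lines (or its
#'   pre-computed eigendecomposition from \code{eigen(A, symmetric=TRUE)}).
#' @return list with \code{geneticVar}, \code{residualVar}, \code{loglik},
#'   \code{h2} (line-level, see above) and \code{converged}.
#' @export
remlUnivariate <- function(y, X, A) {
  y <- as.numeric(y)
  stopifnot(!anyNA(y), nrow(X) == length(y))
  e <- if (is.list(A)) A else eigen(A, symmetric = TRUE)
  d <- pmax(e$values, 0)
  ys <- crossprod(e$vectors, y)[, 1]
  Xs <- crossprod(e$vectors, X)
  vp <- var(y)
  floorV <- 1e-8 * max(vp, .Machine$double.eps)
  if (vp < .Machine$double.eps)
    return(list(geneticVar = floorV, residualVar = floorV,
                loglik = NA_real_, h2 = 0.5, converged = TRUE))
  prof <- function(logh) {
    h <- exp(logh)
    v <- h * d + 1
    w <- 1 / v
    S <- crossprod(Xs, Xs * w)
    b <- solve(S, crossprod(Xs * w, ys))
    r <- ys - Xs %*% b
    n <- length(ys); q <- ncol(Xs)
    se2 <- max(sum(w * r^2) / (n - q), floorV)
    -0.5 * ((n - q) * log(se2) + sum(log(v)) + determinant(S)$modulus[1])
  }
  # the profile over log(ratio) can be multimodal at small n: locate the
  # global maximum on a coarse grid, then refine by Brent search
  lgrid <- seq(log(1e-8), log(1e8), length.out = 121)
  vals <- vapply(lgrid, prof, numeric(1))
  i0 <- which.max(vals)
  lo <- lgrid[max(i0 - 1, 1)]; hi <- lgrid[min(i0 + 1, length(lgrid))]
  opt <- optimize(prof, c(lo, hi), maximum = TRUE, tol = 1e-10)
  h <- exp(opt$maximum)
  v <- h * d + 1; w <- 1 / v
  S <- crossprod(Xs, Xs * w)
  b <- solve(S, crossprod(Xs * w, ys))
  r <- ys - Xs %*% b
  se2 <- max(sum(w * r^2) / (length(ys) - ncol(Xs)), floorV)
  sg2 <- max(h * se2, floorV)
  dbar <- mean(d)
  list(geneticVar = sg2, residualVar = se2,
       loglik = .remlLogLikUni(ys, Xs, d, sg2, se2),
       h2 = dbar * sg2 / (dbar * sg2 + se2), converged = TRUE)
}

# simultaneous diagonalisation: Phi' R0 Phi = I, Phi' G0 Phi = diag(kappa)
.simulDiag <- function(G0, R0) {
  Rc <- chol(projectPSD(R0, 1e-10 * max(diag(R0), 1e-12)))
  Ri <- solve(Rc)                       # Rc^{-1}, upper triangular
  K <- t(Ri) %*% G0 %*% Ri
  e <- eigen((K + t(K)) / 2, symmetric = TRUE)
  list(Phi = Ri %*% e$vectors, PhiInv = t(e$vectors) %*% Rc,
       kappa = pmax(e$values, 0))
}

# EM-REML on the rotated balanced model; Ys = U'Y, Xs = U'X, d = eigenvalues
.emRemlBalanced <- function(Ys, Xs, d, G0, R0, tol = 1e-6, maxit = 200,
                            floorV = 1e-12, trace = FALSE) {
  n <- nrow(Ys); m <- ncol(Ys); q <- ncol(Xs)
  pos <- d > 1e-12
  npos <- sum(pos)
  ll <- -Inf; llPath <- numeric(0)
  events <- character(0)
  it <- 0; converged <- FALSE
  while (it < maxit) {
    it <- it + 1
    sd <- .simulDiag(G0, R0)
    Z <- Ys %*% sd$Phi
    kap <- sd$kappa
    Vu <- Ve <- numeric(m)
    Um <- Em <- matrix(0, n, m)
    llNew <- n * determinant(projectPSD(R0, 1e-300))$modulus[1]
    logS <- 0
    for (j in seq_len(m)) {
      dk <- d * kap[j]
      w <- 1 / (dk + 1)
      Xw <- Xs * w
      S <- crossprod(Xs, Xw)
      Cj <- solve(S)
      bj <- Cj %*% crossprod(Xw, Z[, j])
      r <- Z[, j] - Xs %*% bj
      g <- rowSums((Xs %*% Cj) * Xs)
      Um[, j] <- dk * w * r
      Em[, j] <- w * r
      Vu[j] <- sum((dk * w + (dk * w)^2 * g)[pos] / d[pos])
      Ve[j] <- sum((1 - w) + w^2 * g)
      llNew <- llNew + sum(log(dk + 1)) + sum(w * r^2)
      logS <- logS + determinant(S)$modulus[1]
    }
    llNew <- -0.5 * (llNew + logS - q * determinant(projectPSD(R0, 1e-300))$modulus[1] +
                     (n * m - q * m) * log(2 * pi))
    llPath <- c(llPath, llNew)
    if (is.finite(ll) && abs(llNew - ll) < tol) {
      ll <- llNew; converged <- TRUE; break
    }
    ll <- llNew
    # M-step moments in the diagonalising coordinates
    Usc <- Um[pos, , drop = FALSE] / sqrt(d[pos])
    Ut <- crossprod(Usc)
    diag(Ut) <- diag(Ut) + Vu
    Et <- crossprod(Em)
    diag(Et) <- diag(Et) + Ve
    Gt <- Ut / max(npos, 1)
    Rt <- Et / n
    G0new <- t(sd$PhiInv) %*% Gt %*% sd$PhiInv
    R0new <- t(sd$PhiInv) %*% Rt %*% sd$PhiInv
    G0 <- projectPSD((G0new + t(G0new)) / 2)
    R0 <- projectPSD((R0new + t(R0new)) / 2)
    if (any(diag(G0) < floorV) || any(diag(R0) < floorV)) {
      events <- c(events, sprintf("variance floored at iteration %d", it))
      diag(G0) <- pmax(diag(G0), floorV)
      diag(R0) <- pmax(diag(R0), floorV)
    }
  }
  list(G0 = G0, R0 = R0, loglik = ll, iterations = it, converged = converged,
       llPath = llPath, events = events)
}

# Dense observed-cell EM-REML for unbalanced records. Sized for panels of up
# to a few thousand observed cells.
.emRemlUnbalanced <- function(Y, X, A, G0, R0, tol = 1e-6, maxit = 200,
                              floorV = 1e-12) {
  n <- nrow(Y); m <- ncol(Y); q <- ncol(X)
  obs <- which(!is.na(Y), arr.ind = TRUE)
  li <- obs[, 1]; ei <- obs[, 2]
  yv <- Y[obs]
  N <- length(yv)
  eA <- eigen(A, symmetric = TRUE)
  keep <- eA$values > 1e-10 * max(eA$values)
  U1 <- eA$vectors[, keep, drop = FALSE]
  dA <- eA$values[keep]
  r <- length(dA)
  Afull <- U1 %*% (dA * t(U1))
  D <- matrix(0, N, m * q)
  for (e in seq_len(m)) {
    sel <- ei == e
    D[sel, (e - 1) * q + seq_len(q)] <- X[li[sel], , drop = FALSE]
  }
  sameLine <- outer(li, li, "==")
  Asub <- Afull[li, li]
  U1o <- U1[li, , drop = FALSE]
  ll <- -Inf; llPath <- numeric(0); events <- character(0)
  it <- 0; converged <- FALSE
  while (it < maxit) {
    it <- it + 1
    V <- Asub * G0[cbind(rep(ei, N), rep(ei, each = N))] +
      R0[cbind(rep(ei, N), rep(ei, each = N))] * sameLine
    dim(V) <- c(N, N)
    K <- tryCatch(chol(V), error = function(e) chol(V + diag(1e-8 * mean(diag(V)), N)))
    solveV <- function(x) backsolve(K, forwardsolve(t(K), x))
    WD <- solveV(D)
    S <- crossprod(D, WD)
    Cb <- solve(S)
    beta <- Cb %*% crossprod(WD, yv)
    rv <- yv - D %*% beta
    wr <- solveV(rv)
    llNew <- -0.5 * (2 * sum(log(diag(K))) + sum(rv * wr) +
                     determinant(S)$modulus[1] + (N - m * q) * log(2 * pi))
    llPath <- c(llPath, llNew)
    if (is.finite(ll) && abs(llNew - ll) < tol) {
      ll <- llNew; converged <- TRUE; break
    }
    ll <- llNew
    # genetic moments in the low-rank coordinates (env-major blocks of size r)
    Cu <- matrix(0, r * m, N)
    for (e in seq_len(m))
      Cu[(e - 1) * r + seq_len(r), ] <- (dA * t(U1o)) * rep(G0[e, ei], each = r)
    uhat <- Cu %*% wr
    CuW <- t(solveV(t(Cu)))
    Bu <- CuW %*% D
    M2u <- tcrossprod(uhat) + kronecker(G0, diag(dA, r)) -
      CuW %*% t(Cu) + Bu %*% Cb %*% t(Bu)
    G0new <- matrix(0, m, m)
    for (e in seq_len(m)) for (f in seq_len(m)) {
      ie <- (e - 1) * r + seq_len(r); jf <- (f - 1) * r + seq_len(r)
      G0new[e, f] <- sum(diag(M2u[ie, jf, drop = FALSE]) / dA) / r
    }
    # residual moments per line (line-major blocks of size m)
    Ce <- matrix(0, n * m, N)
    for (o in seq_len(N))
      Ce[(li[o] - 1) * m + seq_len(m), o] <- R0[, ei[o]]
    ehat <- Ce %*% wr
    CeW <- t(solveV(t(Ce)))
    Be <- CeW %*% D
    M2e <- tcrossprod(ehat) + kronecker(diag(n), R0) -
      CeW %*% t(Ce) + Be %*% Cb %*% t(Be)
    R0new <- matrix(0, m, m)
    for (l in seq_len(n)) {
      il <- (l - 1) * m + seq_len(m)
      R0new <- R0new + M2e[il, il]
    }
    R0new <- R0new / n
    G0 <- projectPSD((G0new + t(G0new)) / 2)
    R0 <- projectPSD((R0new + t(R0new)) / 2)
    if (any(diag(G0) < floorV) || any(diag(R0) < floorV)) {
      events <- c(events, sprintf("variance floored at iteration %d", it))
      diag(G0) <- pmax(diag(G0), floorV)
      diag(R0) <- pmax(diag(R0), floorV)
    }
  }
  list(G0 = G0, R0 = R0, loglik = ll, iterations = it, converged = converged,
       llPath = llPath, events = events)
}

#' Bivariate REML for one environment pair
#'
#' EM-REML on the two-column sub-model, initialised from the univariate fits;
#' the off-diagonal initial values split the residual sample covariance of the
#' pair equally between the genetic and residual components (clipped to valid
#' correlations). Used to initialise the multivariate fit. Rows missing either
#' column are dropped.
#'
#' @param Ypair n x 2 phenotype matrix.
#' @param X fixed-effect incidence matrix.
#' @param A relationship matrix.
#' @param init optional list(G0, R0) of 2 x 2 starting values.
#' @param tol,maxit EM convergence controls.
#' @return list with 2 x 2 \code{G0}, \code{R0}, \code{loglik},
#'   \code{iterations}, \code{converged}.
#' @export
remlBivariate <- function(Ypair, X, A, init = NULL, tol = 1e-6, maxit = 200) {
  stopifnot(ncol(Ypair) == 2)
  cc <- stats::complete.cases(Ypair)
  Ypair <- Ypair[cc, , drop = FALSE]
  X <- X[cc, , drop = FALSE]
  A <- A[cc, cc]
  eA <- eigen(A, symmetric = TRUE)
  d <- pmax(eA$values, 0)
  if (is.null(init)) {
    u1 <- remlUnivariate(Ypair[, 1], X, eA)
    u2 <- remlUnivariate(Ypair[, 2], X, eA)
    res <- stats::residuals(stats::lm.fit(X, Ypair))
    s12 <- cov(res)[1, 2]
    g12 <- s12 / 2; r12 <- s12 / 2
    gmax <- 0.95 * sqrt(u1$geneticVar * u2$geneticVar)
    rmax <- 0.95 * sqrt(u1$residualVar * u2$residualVar)
    g12 <- max(min(g12, gmax), -gmax)
    r12 <- max(min(r12, rmax), -rmax)
    init <- list(
      G0 = matrix(c(u1$geneticVar, g12, g12, u2$geneticVar), 2),
      R0 = matrix(c(u1$residualVar, r12, r12, u2$residualVar), 2))
  }
  Ys <- crossprod(eA$vectors, Ypair)
  Xs <- crossprod(eA$vectors, X)
  floorV <- 1e-8 * max(apply(Ypair, 2, var))
  fit <- .emRemlBalanced(Ys, Xs, d, init$G0, init$R0, tol, maxit, floorV)
  fit[c("G0", "R0", "loglik", "iterations", "converged")]
}

# staged initial values: univariate diagonals, bivariate off-diagonals
.stagedInit <- function(Y, X, A) {
  m <- ncol(Y)
  G0 <- matrix(0, m, m); R0 <- matrix(0, m, m)
  for (e in seq_len(m)) {
    oo <- !is.na(Y[, e])
    u <- remlUnivariate(Y[oo, e], X[oo, , drop = FALSE], A[oo, oo])
    G0[e, e] <- u$geneticVar
    R0[e, e] <- u$residualVar
  }
  if (m > 1) {
    for (e in seq_len(m - 1)) for (f in (e + 1):m) {
      b <- remlBivariate(Y[, c(e, f)], X, A, maxit = 50)
      G0[e, f] <- G0[f, e] <- b$G0[1, 2]
      R0[e, f] <- R0[f, e] <- b$R0[1, 2]
    }
  }
  list(G0 = projectPSD(G0, 1e-10 * max(diag(G0))),
       R0 = projectPSD(R0, 1e-10 * max(diag(R0))))
}

#' Multivariate REML for the across-environment covariance matrices
#'
#' EM-REML estimation of the m x m genetic (G0) and residual (R0) covariance
#' of the line-level model with covariance G0 (x) A + R0 (x) I over observed
#' cells. With complete records the fit uses the eigen-rotated fast path;
#' records with missing cells use the dense observed-cell likelihood. The
#' restricted log-likelihood is non-decreasing across iterations; convergence
#' is declared when its change drops below \code{tol} (default 1e-6) or after
#' \code{maxit} iterations (flagged, not an error). With m = 1 the fit
#' delegates to \code{\link{remlUnivariate}}.
#'
#' @param Y n x m phenotype matrix, NA for missing cells; lines missing all
#'   environments are dropped.
#' @param X fixed-effect incidence matrix (n x q).
#' @param A n x n relationship matrix.
#' @param init optional list(G0, R0); defaults to the staged
#'   univariate/bivariate initial values.
#' @param tol,maxit convergence controls.
#' @param keepPath if TRUE the per-iteration restricted log-likelihoods are
#'   attached (used to verify EM monotonicity).
#' @return a \linkS4class{CovarianceEstimate} with structure tag "UG-UR".
#' @export
remlMultivariate <- function(Y, X, A, init = NULL, tol = 1e-6, maxit = 200,
                             keepPath = FALSE) {
  Y <- as.matrix(Y)
  m <- ncol(Y)
  allMiss <- rowSums(!is.na(Y)) == 0
  if (any(allMiss)) {
    Y <- Y[!allMiss, , drop = FALSE]
    X <- X[!allMiss, , drop = FALSE]
    A <- A[!allMiss, !allMiss]
  }
  if (m == 1) {
    oo <- !is.na(Y[, 1])
    u <- remlUnivariate(Y[oo, 1], X[oo, , drop = FALSE], A[oo, oo])
    out <- new("CovarianceEstimate",
               G0 = matrix(u$geneticVar, 1, 1),
               R0 = matrix(u$residualVar, 1, 1),
               structure = "UG-UR", loglik = u$loglik, iterations = 1,
               converged = u$converged)
    if (keepPath) attr(out, "llPath") <- u$loglik
    return(out)
  }
  if (is.null(init)) init <- .stagedInit(Y, X, A)
  floorV <- 1e-8 * max(apply(Y, 2, var, na.rm = TRUE))
  if (anyNA(Y)) {
    fit <- .emRemlUnbalanced(Y, X, A, init$G0, init$R0, tol, maxit, floorV)
  } else {
    eA <- eigen(A, symmetric = TRUE)
    fit <- .emRemlBalanced(crossprod(eA$vectors, Y), crossprod(eA$vectors, X),
                           pmax(eA$values, 0), init$G0, init$R0, tol, maxit,
                           floorV)
  }
  out <- new("CovarianceEstimate", G0 = fit$G0, R0 = fit$R0,
             structure = "UG-UR", loglik = fit$loglik,
             iterations = fit$iterations, converged = fit$converged)
  if (keepPath) attr(out, "llPath") <- fit$llPath
  out
}

#' Staged covariance estimation
#'
#' Convenience wrapper running the full staging the multivariate fit expects:
#' univariate REML per environment for variances, bivariate REML per pair for
#' covariances, then the multivariate EM-REML from those starting values.
#'
#' @inheritParams remlMultivariate
#' @return a \linkS4class{CovarianceEstimate}.
#' @export
estimateCovariances <- function(Y, X, A, tol = 1e-6, maxit = 200) {
  remlMultivariate(Y, X, A, init = NULL, tol = tol, maxit = maxit)
}

#' Impose a covariance structure on an estimate
#'
#' The four structures compared for multi-environment prediction: "SG-" zeroes
#' the off-diagonal of G0 (no genetic covariance), "-SR" zeroes the
#' off-diagonal of R0 (no residual covariance); "UG-UR" leaves the
#' unconstrained estimate untouched. Diagonals are never modified. The
#' operation is idempotent and the G-side and R-side restrictions commute.
#'
#' @param estimate a \linkS4class{CovarianceEstimate} (normally the
#'   unconstrained UG-UR fit).
#' @param tag one of "SG-SR", "SG-UR", "UG-SR", "UG-UR".
#' @return a \linkS4class{CovarianceEstimate} with the requested structure.
#' @export
applyStructure <- function(estimate, tag) {
  stopifnot(is(estimate, "CovarianceEstimate"))
  if (!tag %in% c("SG-SR", "SG-UR", "UG-SR", "UG-UR"))
    stop("unknown covariance structure tag: ", tag)
  G0 <- estimate@G0; R0 <- estimate@R0
  if (substr(tag, 1, 2) == "SG") G0 <- diag(diag(G0), nrow(G0))
  if (substr(tag, 4, 5) == "SR") R0 <- diag(diag(R0), nrow(R0))
  new("CovarianceEstimate", G0 = G0, R0 = R0, structure = tag,
      loglik = estimate@loglik, iterations = estimate@iterations,
      converged = estimate@converged)
}
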