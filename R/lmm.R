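#' Assemble a two-variance-component mixed-model problem
#'
#' Bundles outcome, design and the spectral decomposition of the
#' relationship matrix over the same individuals (rows must already be
#' aligned; listwise-delete and subset the GRM before decomposing). The
#' model is y ~ N(X beta, A sigma_g^2 + I sigma_e^2) — exactly two variance
#' components, one residual and uncorrelated across individuals.
#'
#' @param y numeric outcome.
#' @param X design matrix with intercept, full column rank.
#' @param grm a decomposed \linkS4class{RelatednessMatrix} whose
#'   \code{sampleIds} order matches the rows of \code{y}/\code{X}.
#' @return an \linkS4class{LMMModel}.
#' @export
lmmModel <- function(y, X, grm) {
  stopifnot(is(grm, "RelatednessMatrix"))
  if (!length(grm@eigenValues))
    grm <- eigenDecompose(grm)
  if (length(y) != length(grm@sampleIds))
    stop("y length does not match the relationship matrix")
  new("LMMModel", y = as.numeric(y), X = as.matrix(X),
      U = grm@eigenU, d = grm@eigenValues)
}

#' Rotate a mixed-model problem into independent coordinates
#'
#' Pre-multiplies outcome and design by the transposed eigenvector matrix:
#' y* = U'y, X* = U'X. In the rotated basis observation i has independent
#' variance v_i = d_i sigma_g^2 + sigma_e^2, so the multivariate-normal
#' likelihood factorizes over individuals ("rotating away" the dependence)
#' and the N x N problem becomes N scalar ones.
#'
#' @param model an \linkS4class{LMMModel}.
#' @return list with \code{ystar}, \code{Xstar}, \code{d}.
#' @export
rotate <- function(model) {
  stopifnot(is(model, "LMMModel"))
  list(ystar = drop(crossprod(model@U, model@y)),
       Xstar = crossprod(model@U, model@X),
       d = model@d)
}

## Precomputed pieces of the rotated problem. With a full decomposition
## (k = n) the rotated vectors carry everything; with a low-rank one
## (k < n) the zero-eigenvalue null space enters only through Gram-matrix
## complements (X'X - Xs'Xs etc.), so the likelihood is still exact.
.lmmPre <- function(model) {
  U <- model@U
  k <- ncol(U)
  n <- length(model@y)
  ys <- drop(crossprod(U, model@y))
  Xs <- crossprod(U, model@X)
  pre <- list(ys = ys, Xs = Xs, d = model@d, n = n, k = k, lowRank = k < n)
  if (pre$lowRank) {
    pre$XtX0 <- crossprod(model@X) - crossprod(Xs)
    pre$Xty0 <- drop(crossprod(model@X, model@y)) - drop(crossprod(Xs, ys))
    pre$yty0 <- sum(model@y^2) - sum(ys^2)
  }
  pre
}

## Profile log-likelihood at variance ratio lambda = sigma_g^2 / sigma_e^2:
## given lambda, beta is weighted least squares with weights 1/(d lambda + 1)
## and sigma_e^2 has a closed-form ML solution.
.profileAt <- function(lambda, pre) {
  v1 <- lambda * pre$d + 1
  w <- 1 / v1
  XtW <- pre$Xs * w
  Amat <- crossprod(XtW, pre$Xs)
  b <- drop(crossprod(XtW, pre$ys))
  if (pre$lowRank) {
    Amat <- Amat + pre$XtX0
    b <- b + pre$Xty0
  }
  beta <- tryCatch(drop(solve(Amat, b)), error = function(e) NULL)
  if (is.null(beta))
    return(list(ll = -Inf, beta = rep(NA_real_, ncol(pre$Xs)),
                se2 = NA_real_, lambda = lambda, Amat = Amat))
  r1 <- pre$ys - drop(pre$Xs %*% beta)
  quad <- sum(w * r1^2)
  if (pre$lowRank)
    quad <- quad + pre$yty0 - 2 * sum(beta * pre$Xty0) +
      drop(crossprod(beta, pre$XtX0 %*% beta))
  se2 <- quad / pre$n
  ll <- -0.5 * (pre$n * log(2 * pi) + pre$n * log(se2) + sum(log(v1)) +
                  pre$n)
  list(ll = ll, beta = beta, se2 = se2, lambda = lambda, Amat = Amat)
}

#' Fit the mixed model by full-information maximum likelihood
#'
#' Maximizes the rotated likelihood
#' logL = -1/2 sum_i [log(2 pi v_i) + (y*_i - X*_i beta)^2 / v_i],
#' v_i = d_i sigma_g^2 + sigma_e^2, jointly over (beta, sigma_g^2,
#' sigma_e^2). Given the variance ratio, beta and sigma_e^2 have closed
#' forms, so the optimization is a one-dimensional profile search over
#' log(sigma_g^2 / sigma_e^2): a coarse bracketed grid refined by
#' golden-section (\code{stats::optimize}), with the sigma_g^2 = 0 boundary
#' (ordinary least squares) evaluated explicitly. ML is used, not REML,
#' because likelihoods are compared across fixed-effect specifications.
#'
#' The variance ratio is searched within [exp(gridLo), exp(gridHi)]. A
#' bounded search is deliberate: a relationship matrix standardized with
#' in-sample allele frequencies annihilates the ones vector exactly, and
#' with an intercept in the design the ML likelihood then has an improper
#' ridge (log-likelihood creeping upward forever as the ratio grows while
#' sigma_e^2 collapses on a perfectly fitted coordinate). Solutions pushed
#' to the upper edge are flagged as non-converged.
#' Wald standard errors come from the inverse weighted information of beta
#' at the optimum; p-values for effects should come from \code{\link{lrt}}.
#'
#' @param model an \linkS4class{LMMModel}.
#' @param gridLo,gridHi,gridN coarse grid over log(sigma_g^2/sigma_e^2).
#' @param tol tolerance on the ratio for the golden-section refinement.
#' @return an \linkS4class{LMMFit}.
#' @export
fitFIML <- function(model, gridLo = -15, gridHi = 15, gridN = 61L,
                    tol = 1e-9) {
  pre <- .lmmPre(model)
  nEval <- 0L
  f <- function(loglam) {
    nEval <<- nEval + 1L
    .profileAt(exp(loglam), pre)$ll
  }
  notes <- character()
  flat <- !pre$lowRank && diff(range(pre$d)) < 1e-12
  if (flat) {
    ## A proportional to I: the variance split is unidentifiable; report
    ## the whole variance as residual.
    best <- .profileAt(0, pre)
    notes <- c(notes, "relationship matrix proportional to identity: variance split unidentifiable, total variance reported as sigma_e2")
    lamHat <- 0
    converged <- TRUE
  } else {
    grid <- seq(gridLo, gridHi, length.out = gridN)
    llg <- vapply(grid, f, 0)
    i <- which.max(llg)
    lo <- grid[max(1L, i - 1L)]
    hi <- grid[min(gridN, i + 1L)]
    opt <- stats::optimize(f, c(lo, hi), maximum = TRUE, tol = tol)
    bnd <- .profileAt(0, pre)  # sigma_g^2 = 0 boundary (OLS)
    nEval <- nEval + 1L
    if (bnd$ll >= opt$objective) {
      best <- bnd
      lamHat <- 0
      notes <- c(notes, "boundary solution sigma_g2 = 0")
    } else {
      best <- .profileAt(exp(opt$maximum), pre)
      lamHat <- exp(opt$maximum)
    }
    converged <- TRUE
    if (i == 1L || i == gridN) {
      converged <- lamHat == 0  # ratio ran off the searched bracket
      if (!converged) notes <- c(notes, "variance ratio at the edge of the search bracket")
    }
  }
  se2 <- best$se2
  sg2 <- lamHat * se2
  covB <- se2 * solve(best$Amat)
  beta <- best$beta
  names(beta) <- colnames(pre$Xs)
  n <- pre$n
  if (is.null(names(beta))) names(beta) <- paste0("b", seq_along(beta))
  new("LMMFit", beta = beta, se = sqrt(diag(covB)),
      sigmaG2 = sg2, sigmaE2 = se2, loglik = best$ll,
      converged = converged, nIter = nEval, n = as.integer(n),
      notes = notes)
}

#' Log-likelihood of a mixed-model fit at given parameters
#'
#' Evaluates the rotated log-likelihood at an arbitrary parameter point
#' (useful for comparing against a direct N x N multivariate-normal
#' evaluation).
#'
#' @param model an \linkS4class{LMMModel}.
#' @param beta fixed effects.
#' @param sigmaG2,sigmaE2 variance components.
#' @return scalar log-likelihood.
#' @export
loglikAt <- function(model, beta, sigmaG2, sigmaE2) {
  r <- model@y - drop(model@X %*% beta)
  rs <- drop(crossprod(model@U, r))
  v1 <- model@d * sigmaG2 + sigmaE2
  ll <- -0.5 * sum(log(2 * pi * v1) + rs^2 / v1)
  k <- ncol(model@U)
  n <- length(model@y)
  if (k < n) {  # zero-eigenvalue null space: variance sigmaE2 throughout
    r0 <- sum(r^2) - sum(rs^2)
    ll <- ll - 0.5 * ((n - k) * log(2 * pi * sigmaE2) + r0 / sigmaE2)
  }
  ll
}

#' Likelihood-ratio test between nested mixed-model fits
#'
#' stat = -2 (logL_sub - logL_full), referred to the upper tail of a
#' chi-square with \code{df} degrees of freedom; with df = 1 this is the
#' two-sided test of a single fixed effect. A sub-model likelihood
#' exceeding the full one beyond numerical noise signals non-nesting or an
#' optimizer failure and is an error; tiny negative statistics are clamped
#' to zero.
#'
#' @param full,sub \linkS4class{LMMFit} objects on the same data rows.
#' @param df degrees of freedom (default 1).
#' @return an \linkS4class{LRTResult}.
#' @export
lrt <- function(full, sub, df = 1L) {
  stopifnot(is(full, "LMMFit"), is(sub, "LMMFit"))
  if (full@n != sub@n) stop("full and sub models fit different numbers of rows")
  if (sub@loglik > full@loglik + 1e-6)
    stop("sub-model log-likelihood exceeds the full model: models not nested or optimizer failure")
  stat <- max(0, -2 * (sub@loglik - full@loglik))
  new("LRTResult", stat = stat, df = as.integer(df),
      p = stats::pchisq(stat, df, lower.tail = FALSE))
}
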