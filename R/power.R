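#' Analytic power for a conditional parent/offspring score test
#'
#' Power of the two-sided (chi-square, 1 df) test of a parental genetic
#' risk score on an offspring outcome, conditional on a correlated score
#' (the offspring's; parent and offspring scores correlate 0.5 under
#' random mating). Conditioning inflates the variance of the tested
#' coefficient by 1/(1 - r^2), so the noncentrality is deflated to
#' ncp = n * q2 * (1 - r_cond^2), with q2 the marginal fraction of outcome
#' variance the tested score explains. Power is the upper-tail mass of the
#' noncentral chi-square beyond the central critical value at alpha.
#'
#' @param n number of complete pairs.
#' @param q2 marginal outcome-variance fraction explained by the tested
#'   score, in [0, 1).
#' @param alpha two-sided type-I error rate.
#' @param rCond correlation between tested and conditioning scores
#'   (default 0.5).
#' @return power in [0, 1].
#' @export
powerConditionalGRS <- function(n, q2, alpha = 0.05, rCond = 0.5) {
  stopifnot(n > 0, q2 >= 0, q2 < 1, alpha > 0, alpha < 1,
            rCond > -1, rCond < 1)
  ncp <- n * q2 * (1 - rCond^2)
  crit <- stats::qchisq(1 - alpha, df = 1)
  stats::pchisq(crit, df = 1, ncp = ncp, lower.tail = FALSE)
}

#' Minimum detectable variance fraction
#'
#' Smallest marginal variance fraction q2 whose conditional-test power
#' reaches \code{targetPower}, found by bisection to a relative tolerance
#' of 1e-8. At \code{targetPower = alpha} the answer is zero.
#'
#' @param n,alpha,rCond as in \code{\link{powerConditionalGRS}}.
#' @param targetPower required power, in (alpha, 1).
#' @return q2 fraction.
#' @export
minDetectableVariance <- function(n, alpha = 0.05, targetPower = 0.8,
                                  rCond = 0.5) {
  stopifnot(targetPower >= alpha, targetPower < 1)
  if (targetPower == alpha) return(0)
  lo <- 0; hi <- 1e-6
  while (powerConditionalGRS(n, hi, alpha, rCond) < targetPower && hi < 1)
    hi <- min(hi * 2, 0.999999)
  repeat {
    mid <- (lo + hi) / 2
    if (powerConditionalGRS(n, mid, alpha, rCond) >= targetPower) hi <- mid
    else lo <- mid
    if ((hi - lo) <= 1e-8 * hi) return(hi)
  }
}

#' Path coefficient gamma from birthweight variance explained
#'
#' Under the standardized path model the maternal score explains
#' gamma^2 * lambda1^2 of birthweight variance, so
#' gamma = sqrt(q2_bw / lambda1^2); the sign of lambda1 is irrelevant.
#'
#' @param q2Bw birthweight variance fraction explained by the maternal
#'   score.
#' @param lambda1 factor-to-birthweight path (nonzero).
#' @return gamma.
#' @export
gammaFromBWVariance <- function(q2Bw, lambda1) {
  if (lambda1 == 0) stop("gamma is undefined when lambda1 = 0")
  stopifnot(q2Bw >= 0)
  sqrt(q2Bw / lambda1^2)
}

#' Construct a standardized path model
#'
#' @param gamma,lambda1,lambda2,theta path coefficients (see
#'   \linkS4class{PathModel}).
#' @return a \linkS4class{PathModel}.
#' @export
pathModel <- function(gamma, lambda1, lambda2, theta = 0) {
  new("PathModel", gamma = gamma, lambda1 = lambda1, lambda2 = lambda2,
      theta = theta)
}

#' Outcome variance explained by the maternal score
#'
#' gamma^2 * lambda2^2: the maternal score's effect on the latent
#' intrauterine factor times the factor's effect on the outcome, squared.
#'
#' @param p a \linkS4class{PathModel}.
#' @return variance fraction.
#' @export
outcomeVarianceExplained <- function(p) {
  stopifnot(is(p, "PathModel"))
  p@gamma^2 * p@lambda2^2
}

#' Implied birthweight-outcome correlation
#'
#' lambda1 * lambda2 + theta: the intrauterine pathway common to both
#' phenotypes plus the residual covariance. A result outside [-1, 1] means
#' the model is inconsistent and errors.
#'
#' @param p a \linkS4class{PathModel}.
#' @return correlation.
#' @export
impliedBWOutcomeCorrelation <- function(p) {
  stopifnot(is(p, "PathModel"))
  r <- p@lambda1 * p@lambda2 + p@theta
  if (abs(r) > 1) stop("implied correlation outside [-1, 1]: inconsistent model")
  r
}

#' Monte-Carlo oracle for the conditional-test power
#'
#' Simulates the conditional regression directly: a standardized tested
#' score, a conditioning score correlated \code{rCond} with it, an outcome
#' with the tested score explaining \code{q2} of its variance marginally,
#' and the two-covariate least-squares test of the tested coefficient.
#' Returns the rejection fraction with its binomial standard error.
#'
#' @param n,q2,alpha,rCond as in \code{\link{powerConditionalGRS}}.
#' @param nReps number of simulation replicates (>= 100).
#' @param seed optional seed.
#' @return list with \code{power}, \code{se}, \code{nReps}.
#' @export
powerBySimulation <- function(n, q2, alpha = 0.05, rCond = 0.5,
                              nReps = 500L, seed = NULL) {
  stopifnot(nReps >= 100L)
  if (!is.null(seed)) set.seed(seed)
  beta <- sqrt(q2)
  rej <- logical(nReps)
  for (r in seq_len(nReps)) {
    xt <- stats::rnorm(n)
    xc <- rCond * xt + sqrt(1 - rCond^2) * stats::rnorm(n)
    y <- beta * xt + stats::rnorm(n, 0, sqrt(1 - q2))
    X <- cbind(1, xt, xc)
    fit <- stats::lm.fit(X, y)
    s2 <- sum(fit$residuals^2) / fit$df.residual
    XtXinv <- chol2inv(chol(crossprod(X)))
    z2 <- fit$coefficients[2]^2 / (s2 * XtXinv[2, 2])
    rej[r] <- z2 > stats::qchisq(1 - alpha, 1)
  }
  pw <- mean(rej)
  list(power = pw, se = sqrt(pw * (1 - pw) / nReps), nReps = nReps)
}
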