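test_that("rotation is an orthonormal change of basis", {
  pb <- lmmProblem(70)
  model <- lmmModel(pb$y, pb$X, pb$rm)
  rot <- rotate(model)
  back <- drop(model@U %*% rot$ystar)
  expect_lt(max(abs(back - pb$y)), 1e-10)
})

test_that("rotated log-likelihood equals the direct N x N density", {
  pb <- lmmProblem(71)
  model <- lmmModel(pb$y, pb$X, pb$rm)
  for (par in list(c(0.4, 0.6), c(0.1, 1.2), c(1.5, 0.2))) {
    ll1 <- loglikAt(model, pb$beta, par[1], par[2])
    ll2 <- directMVNLoglik(pb$y, pb$X, pb$beta, par[1], par[2], pb$A)
    expect_lt(abs(ll1 - ll2), 1e-6)
  }
})

test_that("maximized FIML matches a brute-force generic optimizer", {
  pb <- lmmProblem(72)
  fit <- fitFIML(lmmModel(pb$y, pb$X, pb$rm))
  oracle <- bruteFIML(pb$y, pb$X, pb$A)
  expect_lt(abs(fit@loglik - oracle$loglik), 1e-4)
  expect_gte(fit@loglik, oracle$loglik - 1e-6)  # never below the oracle
})

test_that("with an identity relationship matrix the fit reduces to OLS", {
  set.seed(3)
  n <- 120L
  X <- cbind(1, x = rnorm(n))
  y <- drop(X %*% c(1, 0.4)) + rnorm(n)
  rm <- eigenDecompose(new("RelatednessMatrix", A = diag(n),
                           sampleIds = sprintf("i%03d", 1:n), m = 100L,
                           eigenU = matrix(0, 0, 0),
                           eigenValues = numeric()))
  fit <- fitFIML(lmmModel(y, X, rm))
  ols <- lm(y ~ X - 1)
  expect_equal(unname(fit@beta), unname(coef(ols)), tolerance = 1e-8)
  expect_equal(fit@loglik, as.numeric(logLik(ols)), tolerance = 1e-8)
  expect_match(paste(fit@notes, collapse = " "), "unidentifiable")
  expect_equal(fit@sigmaG2, 0)
})

test_that("independent data recover OLS estimates and standard errors", {
  # true sigma_g2 = 0, and a draw whose ML solution sits on the boundary,
  # where the fit must coincide with ordinary least squares
  pb <- lmmProblem(80, n = 150L, sg2 = 0, se2 = 1)
  fit <- fitFIML(lmmModel(pb$y, pb$X, pb$rm))
  expect_identical(fit@sigmaG2, 0)
  expect_match(paste(fit@notes, collapse = " "), "boundary")
  ols <- lm(pb$y ~ pb$X - 1)
  expect_equal(unname(fit@beta), unname(coef(ols)), tolerance = 1e-4)
  olsSE <- sqrt(diag(vcov(ols)) * (ols$df.residual / length(pb$y)))
  expect_equal(unname(fit@se), unname(olsSE), tolerance = 1e-4)
})

test_that("variance components are recovered in a sibship cohort", {
  pb <- lmmProblem(75, n = 800L, sg2 = 0.4, se2 = 0.6)
  fit <- fitFIML(lmmModel(pb$y, pb$X, pb$rm))
  expect_lt(abs(fit@sigmaG2 - 0.4), 0.2)
  expect_lt(abs(fit@sigmaE2 - 0.6), 0.2)
  expect_lt(abs(fit@sigmaG2 + fit@sigmaE2 - 1), 0.15)
})

test_that("permuting individuals leaves estimates unchanged", {
  pb <- lmmProblem(76, n = 80L)
  fit1 <- fitFIML(lmmModel(pb$y, pb$X, pb$rm))
  set.seed(4)
  perm <- sample(length(pb$y))
  rmP <- eigenDecompose(new("RelatednessMatrix",
                            A = pb$A[perm, perm],
                            sampleIds = sampleIds(pb$rm)[perm], m = pb$rm@m,
                            eigenU = matrix(0, 0, 0),
                            eigenValues = numeric()))
  fit2 <- fitFIML(lmmModel(pb$y[perm], pb$X[perm, ], rmP))
  expect_lt(max(abs(fit1@beta - fit2@beta)), 1e-8)
  # variance components agree to the profile-search tolerance
  expect_lt(abs(fit1@sigmaG2 - fit2@sigmaG2), 1e-6)
  expect_lt(abs(fit1@loglik - fit2@loglik), 1e-8)
})

test_that("eigenvector sign flips do not change any statistic", {
  pb <- lmmProblem(77, n = 60L)
  fit1 <- fitFIML(lmmModel(pb$y, pb$X, pb$rm))
  rmF <- pb$rm
  rmF@eigenU <- -rmF@eigenU
  fit2 <- fitFIML(lmmModel(pb$y, pb$X, rmF))
  expect_equal(fit1@beta, fit2@beta, tolerance = 1e-10)
  expect_equal(fit1@loglik, fit2@loglik, tolerance = 1e-10)
})

test_that("the LRT is invariant to affine covariate rescaling", {
  pb <- lmmProblem(78, n = 100L)
  model <- lmmModel(pb$y, pb$X, pb$rm)
  fitF <- fitFIML(model)
  fitS <- fitFIML(new("LMMModel", y = model@y,
                      X = model@X[, -2, drop = FALSE], U = model@U,
                      d = model@d))
  t1 <- lrt(fitF, fitS)
  X2 <- pb$X
  X2[, 2] <- 100 * X2[, 2] + 7
  modelR <- lmmModel(pb$y, X2, pb$rm)
  fitFR <- fitFIML(modelR)
  fitSR <- fitFIML(new("LMMModel", y = modelR@y,
                       X = modelR@X[, -2, drop = FALSE], U = modelR@U,
                       d = modelR@d))
  t2 <- lrt(fitFR, fitSR)
  expect_equal(t1@stat, t2@stat, tolerance = 1e-6)
  expect_equal(fitFR@beta[[2]] * 100, fitF@beta[[2]], tolerance = 1e-5)
})

test_that("LRT arithmetic and guards behave as specified", {
  mk <- function(ll) new("LMMFit", beta = c(b = 1), se = 0.1, sigmaG2 = 0.1,
                         sigmaE2 = 0.9, loglik = ll, converged = TRUE,
                         nIter = 5L, n = 10L, notes = character())
  t0 <- lrt(mk(-100), mk(-100))
  expect_equal(t0@stat, 0)
  expect_equal(t0@p, 1)
  t1 <- lrt(mk(-100), mk(-100 - 3.8415 / 2))
  expect_equal(t1@p, 0.05, tolerance = 1e-4)
  expect_error(lrt(mk(-100), mk(-99)), "nested|failure")
})

test_that("the low-rank fit path reproduces the dense fit exactly", {
  set.seed(30)
  cfg <- simConfig(nFamilies = 100L, nBackgroundSNPs = 150L,
                   dosageMissingRate = 0, seed = 91)
  co <- simulateGenotypes(cfg)
  G <- dosages(co, "offspring")
  n <- nrow(G)
  X <- cbind(1, x = rnorm(n))
  y <- 0.3 * X[, 2] + rnorm(n)
  dn <- eigenDecompose(buildGRM(G))
  lr <- eigenDecompose(buildGRM(G, lowRank = TRUE))
  f1 <- fitFIML(lmmModel(y, X, dn))
  f2 <- fitFIML(lmmModel(y, X, lr))
  expect_equal(f1@loglik, f2@loglik, tolerance = 1e-10)
  expect_equal(f1@beta, f2@beta, tolerance = 1e-10)
  expect_equal(f1@se, f2@se, tolerance = 1e-10)
  expect_equal(f1@sigmaG2, f2@sigmaG2, tolerance = 1e-8)
  expect_equal(loglikAt(lmmModel(y, X, dn), f1@beta, 0.3, 0.7),
               loglikAt(lmmModel(y, X, lr), f1@beta, 0.3, 0.7),
               tolerance = 1e-10)
})
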