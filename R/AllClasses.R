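#' @import methods
NULL

#' TrioCohort: genotypes, pedigree and raw phenotypes for nuclear families
#'
#' Container for a genotyped mother-father-offspring cohort. Dosage matrices
#' hold expected counted-allele counts in [0, 2] (rows = individuals, columns
#' = SNPs; \code{NA} = missing). The pedigree table links individuals to
#' families and roles; the phenotype table holds one row per offspring with
#' the raw survey measurements the preparation pipeline cleans (three blood
#' pressure readings, medication flag, non-fasting blood chemistry,
#' anthropometry, birth-registry fields).
#'
#' @slot mothers,fathers,offspring numeric dosage matrices; rownames are
#'   individual ids, colnames are SNP ids.
#' @slot snpTable data.frame with columns \code{snp_id}, \code{chromosome},
#'   \code{position} (1-based), \code{counted_allele}, \code{other_allele},
#'   \code{freq}, \code{effect_class} (one of \code{maternal_only},
#'   \code{fetal_only}, \code{both}, \code{background}),
#'   \code{maternal_bw_effect}, \code{fetal_bw_effect},
#'   \code{fetal_pleiotropy}.
#' @slot pedigree data.frame with columns \code{family_id},
#'   \code{individual_id}, \code{role} (mother/father/offspring), \code{sex}
#'   (M/F), \code{birth_year}; an optional logical \code{sex_mismatch}
#'   column carries externally determined sex-check failures.
#' @slot phenotypes data.frame of raw offspring measurements (see
#'   \code{\link{simulatePhenotypes}} for the column contract).
#' @slot latents data.frame of simulation ground truth (latent intrauterine
#'   factor, standardized birthweight and outcome); empty for cohorts read
#'   from disk.
#' @export
setClass("TrioCohort", representation(
  mothers = "matrix",
  fathers = "matrix",
  offspring = "matrix",
  snpTable = "data.frame",
  pedigree = "data.frame",
  phenotypes = "data.frame",
  latents = "data.frame"
))

setValidity("TrioCohort", function(object) {
  msg <- character()
  ped <- object@pedigree
  need <- c("family_id", "individual_id", "role", "sex", "birth_year")
  if (!all(need %in% names(ped)))
    msg <- c(msg, "pedigree must have family_id, individual_id, role, sex, birth_year")
  st <- object@snpTable
  for (role in c("mothers", "fathers", "offspring")) {
    m <- slot(object, role)
    if (nrow(m) > 0L) {
      if (ncol(m) != nrow(st))
        msg <- c(msg, sprintf("%s matrix has %d columns but snpTable %d rows",
                              role, ncol(m), nrow(st)))
      if (!identical(colnames(m), st$snp_id))
        msg <- c(msg, sprintf("%s colnames do not match snpTable snp_id", role))
      r1 <- sub("s$", "", role)
      ids <- ped$individual_id[ped$role == r1]
      if (!all(rownames(m) %in% ids))
        msg <- c(msg, sprintf("%s rownames not all present in pedigree as role %s", role, r1))
      ok <- is.na(m) | (m >= 0 & m <= 2)
      if (!all(ok)) msg <- c(msg, sprintf("%s dosages outside [0, 2]", role))
    }
  }
  if (nrow(st) > 0L) {
    if (any(st$freq <= 0 | st$freq >= 1))
      msg <- c(msg, "snpTable freq must lie strictly in (0, 1)")
    if (anyDuplicated(st[, c("chromosome", "position")]))
      msg <- c(msg, "snpTable positions must be unique within chromosome")
    bg <- st$effect_class == "background"
    eff <- abs(st$maternal_bw_effect) + abs(st$fetal_bw_effect) + abs(st$fetal_pleiotropy)
    if (any(bg & eff != 0))
      msg <- c(msg, "background SNPs must have all effect fields zero")
  }
  if (length(msg)) msg else TRUE
})

#' ScoreDefinition: an oriented birthweight SNP set
#'
#' Names a genetic risk score and lists, for each SNP, the allele whose
#' dosage increases the score (the allele associated with increased
#' offspring birthweight in the source GWAS).
#'
#' @slot name score set label, conventionally one of \code{all_autosomal},
#'   \code{maternal_effect}, \code{maternal_only}.
#' @slot entries data.frame with columns \code{snp_id},
#'   \code{bw_increasing_allele}.
#' @export
setClass("ScoreDefinition", representation(
  name = "character",
  entries = "data.frame"
))

setValidity("ScoreDefinition", function(object) {
  msg <- character()
  if (length(object@name) != 1L) msg <- c(msg, "name must be a single string")
  e <- object@entries
  if (!all(c("snp_id", "bw_increasing_allele") %in% names(e)))
    msg <- c(msg, "entries needs snp_id and bw_increasing_allele columns")
  else if (anyDuplicated(e$snp_id))
    msg <- c(msg, "entries snp_id must be unique")
  if (length(msg)) msg else TRUE
})

#' RelatednessMatrix: a GCTA-style genetic relationship matrix
#'
#' Holds the symmetric relationship matrix A over a set of individuals,
#' the number of SNPs it was built from, and (once
#' \code{\link{eigenDecompose}} has been called) its spectral decomposition
#' A = U diag(d) U', the ingredient of the rotated mixed-model likelihood.
#'
#' In the dense representation the matrix A is stored explicitly and its
#' eigendecomposition is full (U is N x N). In the low-rank representation
#' (\code{buildGRM(..., lowRank = TRUE)}) the standardized genotype matrix
#' Z (A = Z Z' / m, rank <= m) is stored instead and the decomposition
#' keeps only the k = rank nonzero-eigenvalue columns; the mixed-model
#' fitter handles the implicit zero-eigenvalue null space exactly, so
#' results are identical while the N x N eigendecomposition is avoided.
#'
#' @slot A symmetric numeric matrix (0 x 0 in the low-rank representation).
#' @slot Z scaled standardized genotype matrix with A = Z Z' / m (0 x 0 in
#'   the dense representation).
#' @slot sampleIds character vector of row/column ids.
#' @slot m integer, number of SNPs used.
#' @slot eigenU orthonormal eigenvector matrix (0 x 0 until decomposed;
#'   N x k in the low-rank representation).
#' @slot eigenValues nonzero eigenvalues in decreasing order, clamped at
#'   zero.
#' @export
setClass("RelatednessMatrix", representation(
  A = "matrix",
  Z = "matrix",
  sampleIds = "character",
  m = "integer",
  eigenU = "matrix",
  eigenValues = "numeric"
), prototype = prototype(
  A = matrix(0, 0, 0), Z = matrix(0, 0, 0), sampleIds = character(),
  m = 0L, eigenU = matrix(0, 0, 0), eigenValues = numeric()
))

setValidity("RelatednessMatrix", function(object) {
  msg <- character()
  A <- object@A
  lowRank <- nrow(A) == 0L
  n <- if (lowRank) nrow(object@Z) else nrow(A)
  if (!lowRank && nrow(A) != ncol(A)) msg <- c(msg, "A must be square")
  if (lowRank && nrow(object@Z) == 0L)
    msg <- c(msg, "either A or Z must be present")
  if (length(object@sampleIds) != n)
    msg <- c(msg, "sampleIds length must match the matrix dimension")
  if (!lowRank && nrow(A) > 0L && max(abs(A - t(A))) > 1e-8)
    msg <- c(msg, "A must be symmetric")
  if (length(object@eigenValues)) {
    if (any(object@eigenValues < 0))
      msg <- c(msg, "eigenvalues must be clamped at >= 0")
    if (nrow(object@eigenU) != n ||
        ncol(object@eigenU) != length(object@eigenValues))
      msg <- c(msg, "eigendecomposition dimensions inconsistent")
    if (!lowRank && length(object@eigenValues) != n)
      msg <- c(msg, "dense decomposition must keep all N eigenvalues")
  }
  if (length(msg)) msg else TRUE
})

#' LMMModel: data for a two-variance-component mixed model
#'
#' Bundles outcome, fixed-effect design and the spectral decomposition of
#' the relationship matrix over the same individuals, i.e. everything the
#' rotated FIML fit needs. The implied covariance is
#' Sigma = A sigma_g^2 + I sigma_e^2.
#'
#' @slot y numeric outcome vector.
#' @slot X fixed-effects design matrix (full column rank, with intercept).
#' @slot U eigenvectors of the relationship matrix; n x n for a dense
#'   decomposition, n x k (k = rank) for a low-rank one, in which case the
#'   remaining n - k eigenvalues are implicitly zero.
#' @slot d eigenvalues matching the columns of U (>= 0).
#' @export
setClass("LMMModel", representation(
  y = "numeric", X = "matrix", U = "matrix", d = "numeric"
))

setValidity("LMMModel", function(object) {
  msg <- character()
  n <- length(object@y)
  if (nrow(object@X) != n) msg <- c(msg, "nrow(X) must equal length(y)")
  if (nrow(object@U) != n || ncol(object@U) > n)
    msg <- c(msg, "U must be n x k with k <= n")
  if (length(object@d) != ncol(object@U))
    msg <- c(msg, "d must have one entry per column of U")
  if (anyNA(object@y) || anyNA(object@X))
    msg <- c(msg, "y and X must be complete (listwise-delete first)")
  if (n > 0L && qr(object@X)$rank < ncol(object@X))
    msg <- c(msg, "X must have full column rank")
  if (length(msg)) msg else TRUE
})

#' LMMFit: a fitted two-variance-component FIML mixed model
#'
#' @slot beta named fixed-effect estimates.
#' @slot se Wald standard errors from the inverse weighted information.
#' @slot sigmaG2 additive genetic variance component (>= 0).
#' @slot sigmaE2 residual variance component (> 0).
#' @slot loglik maximized log-likelihood.
#' @slot converged logical convergence flag.
#' @slot nIter number of profile-likelihood evaluations.
#' @slot n number of observations.
#' @slot notes character vector of fitting remarks (boundary solution,
#'   unidentifiable variance split under an identity relationship matrix).
#' @export
setClass("LMMFit", representation(
  beta = "numeric", se = "numeric", sigmaG2 = "numeric", sigmaE2 = "numeric",
  loglik = "numeric", converged = "logical", nIter = "integer",
  n = "integer", notes = "character"
))

setValidity("LMMFit", function(object) {
  msg <- character()
  if (object@sigmaG2 < 0) msg <- c(msg, "sigmaG2 must be >= 0")
  if (object@sigmaE2 <= 0) msg <- c(msg, "sigmaE2 must be > 0")
  if (!is.finite(object@loglik)) msg <- c(msg, "loglik must be finite")
  if (length(object@beta) != length(object@se))
    msg <- c(msg, "beta and se lengths differ")
  if (length(msg)) msg else TRUE
})

#' LRTResult: a likelihood-ratio test between nested mixed models
#'
#' @slot stat -2 (logL_sub - logL_full), clamped at zero.
#' @slot df degrees of freedom.
#' @slot p upper-tail chi-square probability.
#' @export
setClass("LRTResult", representation(
  stat = "numeric", df = "integer", p = "numeric"
))

setValidity("LRTResult", function(object) {
  msg <- character()
  if (object@stat < 0) msg <- c(msg, "stat must be >= 0 after clamping")
  if (object@p < 0 || object@p > 1) msg <- c(msg, "p must be in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' PathModel: standardized path coefficients of the intrauterine model
#'
#' The latent intrauterine factor is driven by the maternal genetic risk
#' score (path \code{gamma}) and in turn influences offspring birthweight
#' (path \code{lambda1}) and a later-life cardiometabolic outcome (path
#' \code{lambda2}); \code{theta} is the covariance between the residual
#' terms of birthweight and the outcome. All variables are standardized to
#' unit variance.
#'
#' @slot gamma,lambda1,lambda2,theta numeric path coefficients.
#' @export
setClass("PathModel", representation(
  gamma = "numeric", lambda1 = "numeric", lambda2 = "numeric", theta = "numeric"
))

setValidity("PathModel", function(object) {
  msg <- character()
  v <- c(gamma = object@gamma, lambda1 = object@lambda1, lambda2 = object@lambda2)
  if (any(v^2 > 1)) msg <- c(msg, "gamma^2, lambda1^2, lambda2^2 must be <= 1")
  r <- object@lambda1 * object@lambda2 + object@theta
  if (abs(r) > 1) msg <- c(msg, "implied birthweight-outcome correlation outside [-1, 1]")
  if (length(msg)) msg else TRUE
})
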