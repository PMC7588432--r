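# Fixture builders and independent oracles shared across the suite.
# Everything is generated in code; no stored data.

# Minimal valid TrioCohort around explicit dosage matrices.
makeCohort <- function(mothers = NULL, fathers = NULL, offspring = NULL,
                       freq = NULL, chromosome = NULL, position = NULL,
                       counted = NULL, other = NULL, effect_class = NULL,
                       pedigree = NULL, phenotypes = data.frame()) {
  G <- rbind(mothers, fathers, offspring)
  m <- ncol(G)
  if (is.null(freq)) freq <- rep(0.5, m)
  if (is.null(chromosome)) chromosome <- rep(1L, m)
  if (is.null(position)) position <- seq(1e6, by = 5e6, length.out = m)
  if (is.null(counted)) counted <- rep("A", m)
  if (is.null(other)) other <- rep("G", m)
  if (is.null(effect_class)) effect_class <- rep("background", m)
  ids <- if (is.null(colnames(G))) sprintf("snp%05d", seq_len(m)) else colnames(G)
  st <- data.frame(snp_id = ids, chromosome = chromosome,
                   position = position, counted_allele = counted,
                   other_allele = other, freq = freq,
                   effect_class = effect_class,
                   maternal_bw_effect = 0, fetal_bw_effect = 0,
                   fetal_pleiotropy = 0,
                   bw_increasing_allele = ifelse(effect_class == "background",
                                                 NA_character_, counted))
  fixNames <- function(mat, prefix) {
    if (is.null(mat)) return(matrix(0, 0, m, dimnames = list(NULL, ids)))
    if (is.null(rownames(mat)))
      rownames(mat) <- sprintf("%s%03d", prefix, seq_len(nrow(mat)))
    colnames(mat) <- ids
    storage.mode(mat) <- "double"
    mat
  }
  mothers <- fixNames(mothers, "M"); fathers <- fixNames(fathers, "F")
  offspring <- fixNames(offspring, "O")
  if (is.null(pedigree)) {
    mk <- function(mat, role, sex) if (nrow(mat)) data.frame(
      family_id = sprintf("FAM%03d", seq_len(nrow(mat))),
      individual_id = rownames(mat), role = role, sex = sex,
      birth_year = if (role == "offspring") 1980L else 1950L) else NULL
    pedigree <- rbind(mk(mothers, "mother", "F"), mk(fathers, "father", "M"),
                      mk(offspring, "offspring", "F"))
  }
  new("TrioCohort", mothers = mothers, fathers = fathers,
      offspring = offspring, snpTable = st, pedigree = pedigree,
      phenotypes = phenotypes, latents = data.frame())
}

# Fast small simulated cohort for pipeline tests.
smallConfig <- function(seed, nFamilies = 120L, nBackgroundSNPs = 200L, ...) {
  simConfig(nFamilies = nFamilies, nBackgroundSNPs = nBackgroundSNPs,
            seed = seed, ...)
}

# Direct N x N multivariate-normal log-likelihood oracle for
# y ~ N(X beta, A sg2 + I se2), via Cholesky (independent of the rotated
# implementation path).
directMVNLoglik <- function(y, X, beta, sg2, se2, A) {
  n <- length(y)
  Sigma <- sg2 * A + se2 * diag(n)
  R <- chol(Sigma)
  r <- y - drop(X %*% beta)
  z <- backsolve(R, r, transpose = TRUE)
  -0.5 * (n * log(2 * pi) + 2 * sum(log(diag(R))) + sum(z^2))
}

# Brute-force FIML oracle: generic optimizer over (log sg2, log se2) with
# beta profiled out by GLS at every evaluation. No rotation anywhere.
bruteFIML <- function(y, X, A) {
  n <- length(y)
  nll <- function(par) {
    Sigma <- exp(par[1]) * A + exp(par[2]) * diag(n)
    R <- tryCatch(chol(Sigma), error = function(e) NULL)
    if (is.null(R)) return(1e10)
    Xi <- backsolve(R, X, transpose = TRUE)
    yi <- backsolve(R, y, transpose = TRUE)
    if (!all(is.finite(Xi)) || !all(is.finite(yi))) return(1e10)
    fit <- stats::lm.fit(Xi, yi)
    if (anyNA(fit$coefficients)) return(1e10)
    0.5 * (n * log(2 * pi) + 2 * sum(log(diag(R))) + sum(fit$residuals^2))
  }
  v0 <- stats::var(y)
  best <- NULL
  for (start in list(log(c(0.5, 0.5) * v0), log(c(0.05, 0.95) * v0),
                     log(c(0.95, 0.05) * v0))) {
    o <- stats::optim(start, nll, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-12))
    if (is.null(best) || o$value < best$value) best <- o
  }
  list(loglik = -best$value, sg2 = exp(best$par[1]), se2 = exp(best$par[2]))
}

# A small simulated GRM-and-data mixed-model problem. The GRM is built on
# a larger sample and subset to the n analyzed rows: subsetting removes the
# exact null direction that in-sample frequency centering creates, so the
# ML optimum is interior and an unconstrained brute-force oracle is
# meaningful.
lmmProblem <- function(seed, n = 50L, sg2 = 0.4, se2 = 0.6) {
  set.seed(seed)
  cfg <- simConfig(nFamilies = 4L * ceiling(n / 1.6), seed = NULL,
                   nScoreSNPs = c(maternal_only = 0L, both = 0L,
                                  fetal_only = 0L),
                   nBackgroundSNPs = 500L, gamma = 0, polygenicH2 = 0,
                   dosageMissingRate = 0)
  co <- simulateGenotypes(cfg, seed = NULL)
  big <- suppressWarnings(buildGRM(dosages(co, "offspring")))
  rm <- eigenDecompose(subsetGRM(big, sampleIds(big)[seq_len(n)]))
  A <- grmMatrix(rm)
  X <- cbind(1, x1 = rnorm(n), x2 = rnorm(n))
  beta <- c(0.5, 0.3, -0.2)
  L <- chol(sg2 * A + se2 * diag(n))
  y <- drop(X %*% beta) + drop(crossprod(L, rnorm(n)))
  list(y = y, X = X, A = A, rm = rm, beta = beta)
}

# Kinship-style expectation helper: all true parent-offspring id pairs of a
# simulated cohort.
truePOPairs <- function(cohort) {
  ped <- pedigree(cohort)
  off <- ped[ped$role == "offspring", ]
  par <- ped[ped$role != "offspring", ]
  do.call(rbind, lapply(seq_len(nrow(off)), function(i) {
    p <- par[par$family_id == off$family_id[i], "individual_id"]
    if (!length(p)) return(NULL)
    data.frame(id1 = p, id2 = off$individual_id[i])
  }))
}

trueSibPairs <- function(cohort) {
  ped <- pedigree(cohort)
  off <- ped[ped$role == "offspring", ]
  fam <- split(off$individual_id, off$family_id)
  fam <- fam[lengths(fam) > 1L]
  do.call(rbind, lapply(fam, function(ids) {
    cmb <- utils::combn(ids, 2)
    data.frame(id1 = cmb[1, ], id2 = cmb[2, ])
  }))
}

# One fresh end-to-end replicate of the conditional analysis: simulate a
# cohort, QC it, verify pedigree-candidate parent-offspring pairs by
# kinship, build scores and the masked low-rank GRM over the pair
# offspring, and fit the conditional model. Genotypes are redrawn every
# replicate so rejection rates are marginal over cohorts.
freshConditionalRep <- function(cfg, scoreSet = "maternal_effect",
                                exposure = "maternal",
                                conditioning = "offspring") {
  co <- simulatePhenotypes(simulateGenotypes(cfg, seed = NULL), cfg)
  co <- suppressWarnings(variantQC(sampleQC(co)$cohort)$cohort)
  ped <- pedigree(co)
  off <- ped[ped$role == "offspring", ]
  geno <- c(rownames(dosages(co, "mother")), rownames(dosages(co, "father")),
            rownames(dosages(co, "offspring")))
  cand <- rbind(
    data.frame(id1 = paste0(off$family_id, "_M"), id2 = off$individual_id),
    data.frame(id1 = paste0(off$family_id, "_F"), id2 = off$individual_id))
  cand <- cand[cand$id1 %in% geno & cand$id2 %in% geno, ]
  rel <- classifyRelationship(kingKinship(co, pairs = cand))
  pairs <- suppressWarnings(buildPairs(rel, ped))
  role <- if (exposure == "paternal" || conditioning == "paternal")
    "father" else "mother"
  pp <- pairs[pairs$parent_role == role, ]
  scores <- standardScores(co)
  mask <- exclusionMask(snpTable(co), scores$all_autosomal@entries$snp_id)
  grm <- eigenDecompose(buildGRM(
    dosages(co, "offspring")[unique(pp$offspring_id), mask, drop = FALSE],
    lowRank = TRUE))
  st <- snpTable(co)
  iSet <- st$snp_id %in% scores[[scoreSet]]@entries$snp_id
  res <- fitConditionalGRS(co, pp, grm, "sbp", scores[[scoreSet]],
                           exposure = exposure, conditioning = conditioning)
  res$sd_grs <- sqrt(sum(2 * st$freq[iSet] * (1 - st$freq[iSet])))
  res
}

freshConditionalStudy <- function(cfg, nReps, ...) {
  rows <- vector("list", nReps)
  for (r in seq_len(nReps)) rows[[r]] <- freshConditionalRep(cfg, ...)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
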