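test_that("offspring genotypes are Mendel-consistent with parents", {
  cfg <- smallConfig(seed = 11, nFamilies = 60L, nBackgroundSNPs = 50L)
  co <- simulateGenotypes(cfg)
  ped <- pedigree(co)
  off <- ped[ped$role == "offspring", ]
  Gm <- dosages(co, "mother"); Gf <- dosages(co, "father")
  Go <- dosages(co, "offspring")
  m <- Gm[paste0(off$family_id, "_M"), , drop = FALSE]
  f <- Gf[paste0(off$family_id, "_F"), , drop = FALSE]
  o <- Go[off$individual_id, , drop = FALSE]
  lo <- (m == 2) + (f == 2)   # forced transmitted counted alleles
  hi <- (m > 0) + (f > 0)     # maximum transmissible
  ok <- is.na(m) | is.na(f) | is.na(o) | (o >= lo & o <= hi)
  expect_true(all(ok))
  # homozygous 0 x 0 parents can only give dosage 0
  both0 <- !is.na(m) & !is.na(f) & m == 0 & f == 0 & !is.na(o)
  expect_true(all(o[both0] == 0))
})

test_that("trio GRS correlations have the random-mating structure", {
  # 10,000 single-offspring trios at 100 unlinked SNPs
  cfg <- simConfig(nFamilies = 10000L,
                   offspringPerFamily = c(1, rep(0, 7)),
                   nScoreSNPs = c(maternal_only = 100L, both = 0L,
                                  fetal_only = 0L),
                   nBackgroundSNPs = 0L, polygenicH2 = 0,
                   dosageMissingRate = 0, seed = 101)
  co <- simulateGenotypes(cfg)
  sc <- standardScores(co)$maternal_only
  gm <- buildGRS(co, score = sc, role = "mother")
  gf <- buildGRS(co, score = sc, role = "father")
  go <- buildGRS(co, score = sc, role = "offspring")
  ped <- pedigree(co)
  off <- ped[ped$role == "offspring", ]
  gmO <- gm[paste0(off$family_id, "_M")]
  gfO <- gf[paste0(off$family_id, "_F")]
  goO <- go[off$individual_id]
  mcSE <- (1 - 0.25) / sqrt(length(goO))  # SE of r near 0.5
  expect_lt(abs(cor(gmO, goO) - 0.5), 2 * mcSE)
  expect_lt(abs(cor(gfO, goO) - 0.5), 2 * mcSE)
  expect_lt(abs(cor(gmO, gfO)), 2 / sqrt(length(goO)))
})

test_that("offspring allele frequency matches the parental draw", {
  cfg <- simConfig(nFamilies = 10000L,
                   offspringPerFamily = c(1, rep(0, 7)),
                   nScoreSNPs = c(maternal_only = 0L, both = 0L,
                                  fetal_only = 0L),
                   nBackgroundSNPs = 1L, freqRange = c(0.3, 0.3),
                   gamma = 0, polygenicH2 = 0, dosageMissingRate = 0,
                   seed = 7)
  co <- simulateGenotypes(cfg)
  pHat <- mean(dosages(co, "offspring")) / 2
  se <- sqrt(0.3 * 0.7 / (2 * 10000))  # binomial sampling oracle
  expect_lt(abs(pHat - 0.3), 3 * se)
})

test_that("path-model variance fractions are realized in the phenotypes", {
  # pure path model: no direct fetal effects, so the marginal variance of
  # birthweight (outcome) explained by the maternal score is gamma^2
  # lambda1^2 (lambda2^2) exactly
  cfg <- simConfig(nFamilies = 12000L,
                   offspringPerFamily = c(1, rep(0, 7)),
                   nBackgroundSNPs = 0L, polygenicH2 = 0,
                   fetalBWVar = 0, fetalPleioVar = 0,
                   gamma = 0.1414, lambda1 = -0.5, lambda2 = 0.1,
                   dosageMissingRate = 0, phenoMissingRate = 0,
                   outlierRate = 0, seed = 31)
  co <- simulateTrioCohort(cfg)
  lat <- latentValues(co)
  r2bw <- summary(lm(lat$bw_std ~ lat$grs_m_std))$r.squared
  r2out <- summary(lm(lat$outcome_std ~ lat$grs_m_std))$r.squared
  n <- nrow(lat)
  # var of R^2 estimate ~ 4 q2 / n for small q2; allow 3 SE plus null floor
  expect_lt(abs(r2bw - 0.005), 3 * sqrt(4 * 0.005 / n) + 2 / n)
  expect_lt(abs(r2out - 2e-4), 3 * sqrt(4 * 2e-4 / n) + 2 / n)
})

test_that("null path model gives uncorrelated birthweight and outcome", {
  cfg <- simConfig(nFamilies = 4000L, offspringPerFamily = c(1, rep(0, 7)),
                   gamma = 0, theta = 0, fetalBWVar = 0, fetalPleioVar = 0,
                   nBackgroundSNPs = 50L, phenoMissingRate = 0,
                   outlierRate = 0, seed = 13)
  co <- simulateTrioCohort(cfg)
  lat <- latentValues(co)
  expect_lt(abs(cor(lat$bw_std, lat$outcome_std)), 3 / sqrt(nrow(lat)))
})

test_that("a fixed seed reproduces the cohort bit-identically", {
  cfg <- smallConfig(seed = 99, nFamilies = 40L, nBackgroundSNPs = 30L)
  a <- simulateTrioCohort(cfg)
  b <- simulateTrioCohort(cfg)
  expect_identical(dosages(a, "offspring"), dosages(b, "offspring"))
  expect_identical(phenotypes(a), phenotypes(b))
  expect_identical(latentValues(a), latentValues(b))
})

test_that("degenerate configurations are rejected", {
  expect_error(simConfig(nFamilies = 0L), "nonpositive")
  expect_error(simConfig(freqRange = c(0, 0.5)), "freqRange")
  expect_error(simConfig(lambda1 = 0.9, fetalBWVar = 0.5), "residual variance")
  expect_error(simConfig(theta = 0.9), "theta")
})

test_that("medicated individuals' stored readings are unadjusted", {
  cfg <- simConfig(nFamilies = 2000L, offspringPerFamily = c(1, rep(0, 7)),
                   nBackgroundSNPs = 20L, bpMedPrevalence = 0.3,
                   phenoMissingRate = 0, outlierRate = 0, seed = 5)
  co <- simulateTrioCohort(cfg)
  ph <- phenotypes(co)
  medMean <- mean(ph$sbp2[ph$bp_med == 1])
  unmedMean <- mean(ph$sbp2[ph$bp_med == 0])
  # stored on-treatment readings sit ~15 mmHg below untreated ones
  expect_lt(medMean, unmedMean - 10)
})
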