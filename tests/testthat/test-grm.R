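test_that("the GRM entry matches the standardized-product formula by hand", {
  G <- matrix(c(0, 2), 2, 1, dimnames = list(c("a", "b"), "snp00001"))
  expect_warning(rm <- buildGRM(G), "single SNP")
  # p = 0.5: off-diagonal (0-1)(2-1)/(2*0.5*0.5) = -2
  expect_equal(grmMatrix(rm)["a", "b"], -2)
  expect_equal(grmMatrix(rm)["a", "a"], 2)
  expect_equal(rm@m, 1L)
})

test_that("monomorphic SNPs are skipped", {
  G <- cbind(rep(2, 4), c(0, 1, 2, 1), c(0, 0, 0, 0), c(1, 2, 0, 1))
  colnames(G) <- sprintf("s%d", 1:4)
  rm <- buildGRM(G)
  expect_equal(rm@m, 2L)
})

test_that("GRM concentrates at pedigree expectations", {
  cfg <- simConfig(nFamilies = 60L, offspringPerFamily = c(0, 1, rep(0, 6)),
                   nScoreSNPs = c(maternal_only = 0L, both = 0L,
                                  fetal_only = 0L),
                   nBackgroundSNPs = 10000L, gamma = 0, polygenicH2 = 0,
                   dosageMissingRate = 0, seed = 303)
  co <- simulateGenotypes(cfg)
  ped <- pedigree(co)
  off <- ped[ped$role == "offspring", ]
  # joint mother+offspring GRM: parent-offspring expectation 0.5
  ids <- c(rownames(dosages(co, "mother")), off$individual_id)
  A <- grmMatrix(buildGRM(rbind(dosages(co, "mother"),
                                dosages(co, "offspring"))))
  mo <- mapply(function(f, o) A[paste0(f, "_M"), o],
               off$family_id, off$individual_id)
  expect_lt(abs(mean(mo) - 0.5), 0.02)
  # full siblings 0.5
  sib <- trueSibPairs(co)
  sibv <- mapply(function(a, b) A[a, b], sib$id1, sib$id2)
  expect_lt(abs(mean(sibv) - 0.5), 0.03)
  # unrelated ~ 0 up to the small negative shift induced by in-sample
  # allele-frequency centering (order -1/N, amplified by the relatives)
  offA <- A[off$individual_id, off$individual_id]
  fam <- outer(off$family_id, off$family_id, "==")
  un <- offA[upper.tri(offA) & !fam]
  expect_lt(abs(mean(un)), 0.02)
})

test_that("eigendecomposition satisfies its algebraic identities", {
  rm <- new("RelatednessMatrix", A = diag(5), sampleIds = letters[1:5],
            m = 10L, eigenU = matrix(0, 0, 0), eigenValues = numeric())
  e <- eigenDecompose(rm)
  expect_equal(eigenValues(e), rep(1, 5))

  cfg <- smallConfig(seed = 64, nFamilies = 90L, nBackgroundSNPs = 400L)
  co <- simulateGenotypes(cfg)
  rm2 <- buildGRM(dosages(co, "offspring"))
  n <- length(sampleIds(rm2))
  e2 <- suppressWarnings(eigenDecompose(rm2))
  U <- eigenVectors(e2); d <- eigenValues(e2)
  recon <- U %*% (d * t(U))
  expect_lt(max(abs(recon - grmMatrix(rm2))), 1e-8)
  expect_lt(abs(sum(diag(grmMatrix(rm2))) - sum(d)), 1e-6)
  expect_lt(max(abs(crossprod(U) - diag(n))), 1e-10)
  expect_true(all(diff(d) <= 1e-12))  # descending
})

test_that("negative eigenvalues warn and are clamped", {
  A <- matrix(c(1, 2, 2, 1), 2, 2)  # eigenvalues 3 and -1
  rm <- new("RelatednessMatrix", A = A, sampleIds = c("a", "b"), m = 1L,
            eigenU = matrix(0, 0, 0), eigenValues = numeric())
  expect_warning(e <- eigenDecompose(rm), "clamped")
  expect_true(all(eigenValues(e) >= 0))
  bad <- new("RelatednessMatrix", A = diag(2), sampleIds = c("a", "b"),
             m = 1L, eigenU = matrix(0, 0, 0), eigenValues = numeric())
  bad@A[1, 2] <- 0.3  # direct slot write bypasses the validity check
  expect_error(eigenDecompose(bad), "symmetric")
})

test_that("the 1 Mb exclusion mask is inclusive at the boundary", {
  st <- data.frame(
    snp_id = c("score1", "near", "boundary", "clear", "otherchrom"),
    chromosome = c(1, 1, 1, 1, 2),
    position = c(5e6, 5e6 + 999999, 5e6 + 1e6, 5e6 + 1000001, 5e6),
    counted_allele = "A", other_allele = "G", freq = 0.5,
    effect_class = c("maternal_only", rep("background", 4)),
    maternal_bw_effect = 0, fetal_bw_effect = 0, fetal_pleiotropy = 0,
    bw_increasing_allele = c("A", NA, NA, NA, NA))
  kept <- exclusionMask(st, "score1")
  expect_false("score1" %in% kept)   # score SNP itself out
  expect_false("near" %in% kept)     # 999,999 bp away: excluded
  expect_false("boundary" %in% kept) # exactly 1 Mb: excluded
  expect_true("clear" %in% kept)     # 1,000,001 bp away: retained
  expect_true("otherchrom" %in% kept)
})

test_that("low-rank and dense representations agree exactly", {
  cfg <- smallConfig(seed = 65, nFamilies = 80L, nBackgroundSNPs = 120L)
  co <- simulateGenotypes(cfg)
  G <- dosages(co, "offspring")
  dn <- eigenDecompose(buildGRM(G))
  lr <- eigenDecompose(buildGRM(G, lowRank = TRUE))
  expect_lt(max(abs(grmMatrix(dn) - grmMatrix(lr))), 1e-12)
  k <- length(eigenValues(lr))
  expect_lte(k, ncol(G))
  expect_equal(eigenValues(lr), eigenValues(dn)[seq_len(k)], tolerance = 1e-9)
  ids <- sampleIds(dn)[11:40]
  s1 <- eigenDecompose(subsetGRM(dn, ids))
  s2 <- eigenDecompose(subsetGRM(lr, ids))
  expect_lt(max(abs(grmMatrix(s1) - grmMatrix(s2))), 1e-12)
})
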