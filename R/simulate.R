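#' Simulate trio genotypes under random mating and Mendelian transmission
#'
#' Draws a SNP panel (score SNPs in classes \code{maternal_only},
#' \code{both}, \code{fetal_only}, plus \code{background} SNPs with no
#' effect), parental dosages as Binomial(2, freq) under random mating, and
#' offspring dosages by transmitting one allele from each parent
#' (homozygotes transmit their allele; heterozygotes transmit the counted
#' allele with probability 1/2). Siblings share both parents, inducing the
#' cryptic relatedness the mixed model is there to absorb. Genotype
#' missingness is injected after transmission, so Mendelian consistency
#' holds at every non-missing trio-SNP combination.
#'
#' Draw order under the single generator: SNP panel (frequencies, placement,
#' alleles, score orientation), family sizes, offspring sex and birth years,
#' parent birth years, maternal genotypes, paternal genotypes,
#' transmissions, missingness masks.
#'
#' @param config a \code{\link{simConfig}} object.
#' @param seed seed consumed once at entry; defaults to \code{config$seed}.
#'   Use \code{NULL} to continue the current RNG stream.
#' @return a \linkS4class{TrioCohort} with genotypes and pedigree; the
#'   phenotype table is empty until \code{\link{simulatePhenotypes}}.
#' @export
simulateGenotypes <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "SimConfig"))
  if (!is.null(seed)) set.seed(seed)
  st <- .drawSNPPanel(config)
  M <- nrow(st)
  nf <- config$nFamilies
  famSize <- sample(1:8, nf, replace = TRUE, prob = config$offspringPerFamily)
  nOff <- sum(famSize)
  famOf <- rep(seq_len(nf), famSize)

  offSex <- ifelse(stats::runif(nOff) < config$sexRatio, "M", "F")
  byRange <- c(2007 - config$ageRange[2], 2007 - config$ageRange[1])
  offBY <- sample(byRange[1]:byRange[2], nOff, replace = TRUE)
  eldest <- tapply(offBY, famOf, min)
  gapM <- round(stats::runif(nf, config$parentAgeGap[1], config$parentAgeGap[2]))
  gapF <- round(stats::runif(nf, config$parentAgeGap[1], config$parentAgeGap[2]))
  young <- stats::runif(nf) < config$youngParentFrac
  gapM[young] <- sample(5:15, sum(young), replace = TRUE)
  gapF[young] <- sample(5:15, sum(young), replace = TRUE)

  p <- st$freq
  Gm <- matrix(stats::rbinom(nf * M, 2L, rep(p, each = nf)), nf, M)
  Gf <- matrix(stats::rbinom(nf * M, 2L, rep(p, each = nf)), nf, M)
  Gme <- Gm[famOf, , drop = FALSE]
  Gfe <- Gf[famOf, , drop = FALSE]
  Go <- matrix(stats::rbinom(nOff * M, 1L, Gme / 2) +
                 stats::rbinom(nOff * M, 1L, Gfe / 2), nOff, M)

  mids <- sprintf("F%05d_M", seq_len(nf))
  fids <- sprintf("F%05d_F", seq_len(nf))
  oids <- sprintf("F%05d_O%d", famOf,
                  unlist(lapply(famSize, seq_len), use.names = FALSE))
  storage.mode(Gm) <- storage.mode(Gf) <- storage.mode(Go) <- "double"
  if (config$dosageMissingRate > 0) {
    Gm[stats::runif(length(Gm)) < config$dosageMissingRate] <- NA
    Gf[stats::runif(length(Gf)) < config$dosageMissingRate] <- NA
    Go[stats::runif(length(Go)) < config$dosageMissingRate] <- NA
  }
  dimnames(Gm) <- list(mids, st$snp_id)
  dimnames(Gf) <- list(fids, st$snp_id)
  dimnames(Go) <- list(oids, st$snp_id)

  fam <- sprintf("F%05d", seq_len(nf))
  ped <- rbind(
    data.frame(family_id = fam, individual_id = mids, role = "mother",
               sex = "F", birth_year = as.integer(eldest - gapM)),
    data.frame(family_id = fam, individual_id = fids, role = "father",
               sex = "M", birth_year = as.integer(eldest - gapF)),
    data.frame(family_id = sprintf("F%05d", famOf), individual_id = oids,
               role = "offspring", sex = offSex, birth_year = offBY)
  )
  rownames(ped) <- NULL
  new("TrioCohort", mothers = Gm, fathers = Gf, offspring = Go,
      snpTable = st, pedigree = ped,
      phenotypes = data.frame(), latents = data.frame())
}

## SNP panel: blocks of score classes then background; unlinked loci spread
## over 22 autosomes; per-SNP effects give equal standardized contributions
## within a class. Effects are stored per counted allele; the score
## orientation (bw_increasing_allele) is randomized against the counted
## allele so downstream orientation handling is exercised.
.drawSNPPanel <- function(config) {
  ns <- config$nScoreSNPs
  M <- sum(ns) + config$nBackgroundSNPs
  cls <- rep(c("maternal_only", "both", "fetal_only", "background"),
             c(ns[["maternal_only"]], ns[["both"]], ns[["fetal_only"]],
               config$nBackgroundSNPs))
  freq <- stats::runif(M, config$freqRange[1], config$freqRange[2])
  chrom <- sample(1:22, M, replace = TRUE)
  pos <- sample.int(249000000L, M, replace = TRUE)
  while (anyDuplicated(paste(chrom, pos))) {
    d <- duplicated(paste(chrom, pos))
    pos[d] <- pos[d] + 1L
  }
  bases <- c("A", "C", "G", "T")
  a1 <- sample(bases, M, replace = TRUE)
  a2 <- vapply(a1, function(b) sample(setdiff(bases, b), 1L), "")
  sflip <- sample(c(1, -1), M, replace = TRUE)

  isScore <- cls != "background"
  isMat <- cls %in% c("maternal_only", "both")
  isFet <- cls %in% c("both", "fetal_only")
  sdDos <- sqrt(2 * freq * (1 - freq))
  ## maternal path: per-SNP share of the latent driver. The oriented
  ## maternal GRS over maternal-effect SNPs is standardized, then scaled by
  ## gamma * lambda1 to act on birthweight.
  matEff <- numeric(M)
  if (any(isMat)) {
    sdGRS <- sqrt(sum(sdDos[isMat]^2))
    matEff[isMat] <- sflip[isMat] * config$gamma * config$lambda1 / sdGRS
  }
  fetBW <- numeric(M)
  fetPl <- numeric(M)
  if (any(isFet)) {
    nFet <- sum(isFet)
    fetBW[isFet] <- sflip[isFet] * sqrt(config$fetalBWVar / nFet) / sdDos[isFet]
    fetPl[isFet] <- sflip[isFet] * sqrt(config$fetalPleioVar / nFet) / sdDos[isFet]
  }
  data.frame(
    snp_id = sprintf("snp%05d", seq_len(M)),
    chromosome = chrom, position = pos,
    counted_allele = unname(a1), other_allele = unname(a2),
    freq = freq, effect_class = cls,
    maternal_bw_effect = matEff, fetal_bw_effect = fetBW,
    fetal_pleiotropy = fetPl,
    bw_increasing_allele = ifelse(isScore,
                                  ifelse(sflip > 0, unname(a1), unname(a2)),
                                  NA_character_)
  )
}

## Oriented dosage: counted-allele dosage if the counted allele is the
## score allele, else 2 - dosage. `q` is the oriented-allele frequency.
.orient <- function(mat, st, idx) {
  s <- ifelse(st$bw_increasing_allele[idx] == st$counted_allele[idx], 1, -1)
  d <- mat[, idx, drop = FALSE]
  d[, s < 0] <- 2 - d[, s < 0, drop = FALSE]
  q <- ifelse(s > 0, st$freq[idx], 1 - st$freq[idx])
  list(d = d, q = q)
}

## Mean-impute missing entries to 2q, column-wise.
.imputeTo <- function(d, q2) {
  if (anyNA(d)) {
    nai <- which(is.na(d), arr.ind = TRUE)
    d[nai] <- q2[nai[, 2]]
  }
  d
}

#' Simulate raw phenotypes from genotypes under the path model
#'
#' Fills the cohort phenotype table. The latent intrauterine factor is
#' U = gamma * z(GRS_m) + e, with GRS_m the mother's oriented unweighted
#' score over the maternal-effect SNPs (standardized by its theoretical
#' moments) and var(e) = 1 - gamma^2; one factor is drawn per pregnancy.
#' Standardized birthweight is lambda1 * U + direct fetal effects +
#' residual; the standardized outcome is lambda2 * U + fetal pleiotropy +
#' background polygenic score + residual, with residual covariance theta.
#'
#' The raw table then reproduces survey artifacts: the outcome is written
#' onto systolic blood pressure (three readings around the latent level,
#' with the later readings a downstream pipeline must average), medicated
#' individuals' stored readings are their on-treatment values (no +15/+10
#' pre-adjustment), diastolic BP and the blood chemistry carry partial
#' loadings on the same outcome, glucose/triglycerides/BMI are lognormal,
#' and birth-registry fields (gestation, delivery and malformation flags,
#' birthweight in grams) plus missingness and occasional gross outliers are
#' injected.
#'
#' @param cohort a \linkS4class{TrioCohort} with genotypes present.
#' @param config the \code{\link{simConfig}} used for the genotypes.
#' @param seed optional seed; default \code{NULL} continues the RNG stream
#'   (so replicate phenotype redraws on a fixed cohort are natural).
#' @return the cohort with \code{phenotypes} and \code{latents} filled.
#' @export
simulatePhenotypes <- function(cohort, config, seed = NULL) {
  stopifnot(is(cohort, "TrioCohort"), inherits(config, "SimConfig"))
  if (!is.null(seed)) set.seed(seed)
  if (nrow(cohort@offspring) == 0L) stop("cohort has no offspring genotypes")
  st <- cohort@snpTable
  ped <- cohort@pedigree
  off <- ped[ped$role == "offspring", ]
  off <- off[match(rownames(cohort@offspring), off$individual_id), ]
  nOff <- nrow(off)
  momOf <- paste0(off$family_id, "_M")

  ## latent driver: standardized oriented maternal GRS (maternal-effect SNPs)
  iMat <- which(st$effect_class %in% c("maternal_only", "both"))
  if (length(iMat)) {
    om <- .orient(cohort@mothers, st, iMat)
    dm <- .imputeTo(om$d, 2 * om$q)
    grsM <- rowSums(dm)
    zM <- (grsM - sum(2 * om$q)) / sqrt(sum(2 * om$q * (1 - om$q)))
  } else zM <- numeric(nrow(cohort@mothers))
  zMo <- zM[match(momOf, rownames(cohort@mothers))]
  zMo[is.na(zMo)] <- 0  # mother removed by QC: latent driven by noise only

  U <- config$gamma * zMo + stats::rnorm(nOff, 0, sqrt(1 - config$gamma^2))

  iFet <- which(st$effect_class %in% c("both", "fetal_only"))
  fetBW <- fetPl <- numeric(nOff)
  if (length(iFet)) {
    ofo <- .orient(cohort@offspring, st, iFet)
    do <- .imputeTo(ofo$d, 2 * ofo$q)
    dc <- sweep(do, 2, 2 * ofo$q)
    s <- ifelse(st$bw_increasing_allele[iFet] == st$counted_allele[iFet], 1, -1)
    fetBW <- drop(dc %*% (st$fetal_bw_effect[iFet] * s))
    fetPl <- drop(dc %*% (st$fetal_pleiotropy[iFet] * s))
  }
  iBg <- which(st$effect_class == "background")
  poly <- numeric(nOff)
  if (length(iBg) && config$polygenicH2 > 0) {
    db <- .imputeTo(cohort@offspring[, iBg, drop = FALSE], 2 * st$freq[iBg])
    w <- sqrt(config$polygenicH2 / length(iBg)) /
      sqrt(2 * st$freq[iBg] * (1 - st$freq[iBg]))
    poly <- drop(sweep(db, 2, 2 * st$freq[iBg]) %*% w)
  }

  eBW <- stats::rnorm(nOff, 0, sqrt(config$residBWVar))
  condVar <- config$residOutVar - config$theta^2 / max(config$residBWVar, 1e-12)
  eOut <- if (config$residBWVar > 0)
    (config$theta / config$residBWVar) * eBW + stats::rnorm(nOff, 0, sqrt(max(condVar, 0)))
  else stats::rnorm(nOff, 0, sqrt(config$residOutVar))

  bwStd <- config$lambda1 * U + fetBW + eBW
  outStd <- config$lambda2 * U + fetPl + poly + eOut

  ## survey layer ------------------------------------------------------
  occ <- ifelse(stats::runif(nOff) < config$occasionProb3, 3L, 2L)
  age <- ifelse(occ == 3L, 2007L, 1996L) - off$birth_year + stats::runif(nOff, 0, 0.9)
  tooYoung <- age < config$ageRange[1]
  occ[tooYoung] <- 3L
  age[tooYoung] <- 2007L - off$birth_year[tooYoung] + stats::runif(sum(tooYoung), 0, 0.9)

  med <- stats::runif(nOff) < config$bpMedPrevalence
  sbpLevel <- 128.3 + 17.3 * outStd - 15 * med
  zDbp <- 0.6 * outStd + sqrt(1 - 0.36) * stats::rnorm(nOff)
  dbpLevel <- 73.9 + 11.9 * zDbp - 10 * med
  rd <- function(level) level + stats::rnorm(nOff, 0, 3)
  sbp <- cbind(rd(sbpLevel), rd(sbpLevel), rd(sbpLevel))
  dbp <- cbind(rd(dbpLevel), rd(dbpLevel), rd(dbpLevel))
  twoOnly <- stats::runif(nOff) < config$twoReadingsFrac
  sbp[twoOnly, 3] <- NA
  dbp[twoOnly, 3] <- NA

  mix <- function(load) load * outStd + sqrt(1 - load^2) * stats::rnorm(nOff)
  spike <- function(z) {  # gross outliers on the analysis (log/z) scale
    k <- stats::runif(nOff) < config$outlierRate
    z[k] <- z[k] + sample(c(-1, 1), sum(k), replace = TRUE) * stats::runif(sum(k), 4.5, 8)
    z
  }
  glucose <- exp(1.62 + 0.20 * spike(mix(0.25)))
  tc <- 5.31 + 1.08 * mix(0.20)
  hdl <- pmax(1.33 + 0.33 * mix(-0.15), 0.2)  # floored: HDL cannot be near zero
  tg <- exp(0.14 + 0.50 * spike(mix(0.25)))
  bmi <- exp(3.24 + 0.15 * spike(mix(0.30)))
  height <- ifelse(off$sex == "M", stats::rnorm(nOff, 1.79, 0.065),
                   stats::rnorm(nOff, 1.66, 0.060))
  weight <- bmi * height^2

  bwG <- 3570 + 482 * bwStd
  gest <- round(stats::rnorm(nOff, config$gestationMeanSD[1], config$gestationMeanSD[2]))
  rr <- config$registryRates
  csec <- as.integer(stats::runif(nOff) < rr$csection_or_induced)
  mult <- as.integer(stats::runif(nOff) < rr$multiple_birth)
  malf <- as.integer(stats::runif(nOff) < rr$malformation)

  ph <- data.frame(
    individual_id = off$individual_id,
    sbp1 = sbp[, 1], sbp2 = sbp[, 2], sbp3 = sbp[, 3],
    dbp1 = dbp[, 1], dbp2 = dbp[, 2], dbp3 = dbp[, 3],
    bp_med = as.integer(med),
    glucose = glucose, tc = tc, hdl = hdl, tg = tg,
    weight_kg = weight, height_m = height,
    birthweight_g = bwG, gestation_days = gest,
    csection_or_induced = csec, multiple_birth = mult, malformation = malf,
    age = age, sex = off$sex, occasion = occ
  )
  if (config$phenoMissingRate > 0) {
    miss <- c("sbp1", "sbp2", "sbp3", "dbp1", "dbp2", "dbp3", "glucose",
              "tc", "hdl", "tg", "weight_kg", "height_m",
              "birthweight_g", "gestation_days")
    for (cc in miss)
      ph[[cc]][stats::runif(nOff) < config$phenoMissingRate] <- NA
  }
  cohort@phenotypes <- ph
  cohort@latents <- data.frame(individual_id = off$individual_id,
                               grs_m_std = zMo, U = U,
                               bw_std = bwStd, outcome_std = outStd)
  cohort
}

#' Simulate a complete trio cohort (genotypes + phenotypes)
#'
#' Seeds the generator once from \code{config$seed}, then runs
#' \code{\link{simulateGenotypes}} and \code{\link{simulatePhenotypes}} in
#' sequence on the single stream, so a fixed seed yields a bit-identical
#' cohort.
#'
#' @param config a \code{\link{simConfig}}.
#' @return a complete \linkS4class{TrioCohort}.
#' @export
simulateTrioCohort <- function(config) {
  if (!is.null(config$seed)) set.seed(config$seed)
  simulatePhenotypes(simulateGenotypes(config, seed = NULL), config)
}
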