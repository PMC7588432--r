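#' Simulation configuration for a trio cohort
#'
#' Collects and validates every parameter of the generative model: cohort
#' layout, SNP panel, the standardized path model (maternal GRS -> latent
#' intrauterine factor -> birthweight / outcome), direct fetal genotype
#' effects, the background polygenic component, and the survey artifacts
#' injected into the raw phenotype table.
#'
#' The path model works on standardized scales: the latent factor is
#' U = gamma * z(GRS_m) + e with var(e) = 1 - gamma^2; standardized
#' birthweight is lambda1 * U plus direct fetal effects plus residual;
#' the standardized outcome is lambda2 * U plus fetal pleiotropy plus a
#' polygenic term built from the background SNPs plus residual, and the two
#' residuals have covariance \code{theta}.
#'
#' @param nFamilies number of families.
#' @param offspringPerFamily probability vector over 1..8 offspring per
#'   family (normalized internally).
#' @param nScoreSNPs named integer vector with elements \code{maternal_only},
#'   \code{both}, \code{fetal_only}. The defaults (31, 40, 133) give the
#'   standard score-set sizes 204 (all), 71 (maternal effect) and 31
#'   (maternal-only).
#' @param nBackgroundSNPs SNPs with no score effect, used for the GRM and
#'   the polygenic outcome component.
#' @param freqRange interval for drawing counted-allele frequencies.
#' @param gamma,lambda1,lambda2,theta standardized path coefficients (see
#'   \linkS4class{PathModel}). Defaults are the illustrative values
#'   gamma = 0.1414 (maternal GRS explains 0.5\% of birthweight variance at
#'   lambda1 = -0.5), lambda2 = 0.1, theta = 0.
#' @param fetalBWVar birthweight variance explained by direct fetal
#'   genotype effects (classes \code{both} + \code{fetal_only}).
#' @param fetalPleioVar outcome variance explained by direct fetal
#'   pleiotropy (the fetal-insulin-style pathway).
#' @param polygenicH2 outcome variance from the background polygenic score.
#' @param ageRange offspring age range (years) at the latest survey.
#' @param sexRatio probability an offspring is male.
#' @param bpMedPrevalence prevalence of blood-pressure medication use;
#'   stored readings of medicated individuals are their (lower) on-treatment
#'   values, so the +15/+10 mmHg adjustment is exercised downstream.
#' @param twoReadingsFrac fraction of offspring with only two BP readings.
#' @param occasionProb3 probability the measurement occasion is the later
#'   survey wave (occasion 3 vs 2).
#' @param registryRates named list of birth-registry flag rates:
#'   \code{csection_or_induced}, \code{multiple_birth}, \code{malformation}.
#' @param gestationMeanSD mean and SD of gestation length in days.
#' @param phenoMissingRate per-cell missingness rate for raw phenotypes.
#' @param outlierRate rate of gross (+5 SD on the analysis scale) outliers
#'   injected into the trimmed variables.
#' @param dosageMissingRate per-cell genotype missingness rate.
#' @param youngParentFrac fraction of families whose recorded parent birth
#'   years leave a <= 15-year gap to the eldest offspring (exercises the
#'   birth-year pair filter).
#' @param parentAgeGap range (years) by which parents predate the eldest
#'   offspring in ordinary families.
#' @param seed integer seed; a single generator drives all draws.
#' @return a validated list of class \code{SimConfig}.
#' @export
simConfig <- function(nFamilies = 500L,
                      offspringPerFamily = 0.55^(0:7),
                      nScoreSNPs = c(maternal_only = 31L, both = 40L,
                                     fetal_only = 133L),
                      nBackgroundSNPs = 300L,
                      freqRange = c(0.1, 0.9),
                      gamma = 0.1414, lambda1 = -0.5, lambda2 = 0.1,
                      theta = 0,
                      fetalBWVar = 0.05, fetalPleioVar = 0.01,
                      polygenicH2 = 0.2,
                      ageRange = c(19, 75), sexRatio = 0.484,
                      bpMedPrevalence = 0.15, twoReadingsFrac = 0.12,
                      occasionProb3 = 0.7,
                      registryRates = list(csection_or_induced = 0.2,
                                           multiple_birth = 0.019,
                                           malformation = 0.03),
                      gestationMeanSD = c(281, 11),
                      phenoMissingRate = 0.02, outlierRate = 0.002,
                      dosageMissingRate = 0.005,
                      youngParentFrac = 0.01,
                      parentAgeGap = c(25, 40),
                      seed = NULL) {
  cfg <- as.list(environment())
  stopifnot(length(offspringPerFamily) == 8L, all(offspringPerFamily >= 0),
            sum(offspringPerFamily) > 0)
  cfg$offspringPerFamily <- offspringPerFamily / sum(offspringPerFamily)
  if (nFamilies < 1L || nBackgroundSNPs < 0L || any(nScoreSNPs < 0L) ||
      sum(nScoreSNPs) + nBackgroundSNPs < 1L)
    stop("SimConfig: nonpositive cohort or SNP counts")
  if (!all(c("maternal_only", "both", "fetal_only") %in% names(nScoreSNPs)))
    stop("SimConfig: nScoreSNPs must name maternal_only, both, fetal_only")
  if (length(freqRange) != 2L || freqRange[1] <= 0 || freqRange[2] >= 1 ||
      freqRange[1] > freqRange[2])
    stop("SimConfig: degenerate freqRange; need 0 < lo <= hi < 1")
  fr <- c(fetalBWVar, fetalPleioVar, polygenicH2,
          bpMedPrevalence, twoReadingsFrac, occasionProb3,
          phenoMissingRate, outlierRate, dosageMissingRate, youngParentFrac,
          sexRatio, unlist(registryRates))
  if (any(fr < 0 | fr > 1))
    stop("SimConfig: all rates and variance fractions must lie in [0, 1]")
  if (gamma^2 > 1)
    stop("SimConfig: gamma^2 must be <= 1")
  cfg$residBWVar <- 1 - lambda1^2 - fetalBWVar
  cfg$residOutVar <- 1 - lambda2^2 - fetalPleioVar - polygenicH2
  if (cfg$residBWVar < 0 || cfg$residOutVar < 0)
    stop("SimConfig: implied residual variance is negative")
  if (abs(lambda1 * lambda2 + theta) > 1)
    stop("SimConfig: |lambda1*lambda2 + theta| must be <= 1")
  if (cfg$residBWVar * cfg$residOutVar < theta^2)
    stop("SimConfig: theta exceeds what the residual variances allow")
  class(cfg) <- "SimConfig"
  cfg
}

#' @export
print.SimConfig <- function(x, ...) {
  cat("SimConfig:", x$nFamilies, "families;",
      sum(x$nScoreSNPs), "score SNPs +", x$nBackgroundSNPs, "background\n")
  cat("  path model: gamma =", x$gamma, "lambda1 =", x$lambda1,
      "lambda2 =", x$lambda2, "theta =", x$theta, "\n")
  cat("  fetal bw var =", x$fetalBWVar, " fetal pleiotropy var =",
      x$fetalPleioVar, " polygenic h2 =", x$polygenicH2, "\n")
  invisible(x)
}
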