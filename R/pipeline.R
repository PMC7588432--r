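## Covariate design helper: indicator-codes sex and occasion, drops
## zero-variance columns (e.g. a stratum measured at one occasion only).
.covariateDesign <- function(age, sex, occasion) {
  X <- cbind(age = age,
             sexM = as.numeric(sex == "M"),
             occasion3 = as.numeric(occasion == 3))
  keep <- apply(X, 2L, function(col) stats::var(col) > 0)
  X[, keep, drop = FALSE]
}

## Decomposed GRM over exactly `ids`, reusing a supplied decomposition
## when the sample set already matches (replicate designs redraw
## phenotypes on a fixed cohort and hit this path).
.eigenFor <- function(grm, ids) {
  if (length(grm@eigenValues) && identical(grm@sampleIds, ids)) return(grm)
  eigenDecompose(subsetGRM(grm, ids))
}

## Fit outcome ~ X via rotated FIML and LRT each column in `testCols`
## against the model without it.
.fitAndTest <- function(y, X, grm, ids, testCols) {
  g <- .eigenFor(grm, ids)
  model <- lmmModel(y, X, g)
  full <- fitFIML(model)
  out <- lapply(testCols, function(cc) {
    j <- match(cc, colnames(X))
    sub <- fitFIML(new("LMMModel", y = model@y,
                       X = model@X[, -j, drop = FALSE],
                       U = model@U, d = model@d))
    t <- lrt(full, sub, df = 1L)
    list(effect = full@beta[[cc]], se = full@se[[j]], p = t@p,
         stat = t@stat)
  })
  names(out) <- testCols
  list(full = full, tests = out)
}

#' Phenotypic birthweight model (quadratic)
#'
#' For each cardiometabolic outcome, fits
#' outcome ~ birthweight(kg) + birthweight^2 + age + sex + occasion on the
#' registry-eligible offspring of the analysis pairs, through the rotated
#' mixed model, and reports the linear and quadratic birthweight effects
#' with likelihood-ratio p-values. Outcomes stay in their native (analysis
#' scale) units.
#'
#' @param cohort a \linkS4class{TrioCohort} with phenotypes.
#' @param pairs analysis pairs from \code{\link{buildPairs}} (one parent
#'   role).
#' @param grm \linkS4class{RelatednessMatrix} covering the pair offspring.
#' @param outcomes outcome column names of the prepared battery.
#' @param battery optionally a precomputed \code{\link{preparePhenotypes}}
#'   table.
#' @param minN minimum eligible sample size (refuses below 100).
#' @return data.frame with one row per outcome: \code{outcome}, \code{n},
#'   \code{effect_bw}, \code{se_bw}, \code{p_bw}, \code{effect_bw2},
#'   \code{se_bw2}, \code{p_bw2}.
#' @export
fitPhenotypicBWModel <- function(cohort, pairs, grm,
                                 outcomes = c("sbp", "dbp", "glucose", "tc",
                                              "ldl", "hdl", "tg", "bmi"),
                                 battery = NULL, minN = 100L) {
  if (is.null(battery)) battery <- preparePhenotypes(cohort)
  b <- battery[match(pairs$offspring_id, battery$individual_id), ]
  elig <- !is.na(b$birthweight_kg) & b$bw_eligible
  if (sum(elig) < minN)
    stop("only ", sum(elig), " eligible offspring with birthweight; ",
         "refusing to fit (minimum ", minN, ")")
  b <- b[elig, ]
  res <- lapply(outcomes, function(oc) {
    ok <- stats::complete.cases(b[, c(oc, "age", "sex", "occasion")])
    d <- b[ok, ]
    bw <- d$birthweight_kg
    X <- cbind("(Intercept)" = 1, bw = bw, bw2 = bw^2,
               .covariateDesign(d$age, d$sex, d$occasion))
    ft <- .fitAndTest(d[[oc]], X, grm, d$individual_id, c("bw", "bw2"))
    data.frame(outcome = oc, n = nrow(d),
               effect_bw = ft$tests$bw$effect, se_bw = ft$tests$bw$se,
               p_bw = ft$tests$bw$p,
               effect_bw2 = ft$tests$bw2$effect, se_bw2 = ft$tests$bw2$se,
               p_bw2 = ft$tests$bw2$p)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Conditional genetic risk score association
#'
#' The primary analysis: standardized offspring outcome regressed on the
#' exposure score conditional on the other family member's score,
#' outcome* ~ GRS_exposure + GRS_conditioning + age + sex + occasion,
#' fitted through the rotated FIML mixed model over the offspring
#' relationship matrix. The outcome is z-scored within the analysis
#' sample; scores stay on the allele-count scale, so the effect is in
#' standardized outcome units per allele. The p-value is the
#' likelihood-ratio test dropping the exposure term.
#'
#' Exposure/conditioning configurations: maternal|offspring (mother
#' pairs), paternal|offspring (father pairs), offspring|maternal (mother
#' pairs); the pair set is chosen by the parental role involved.
#'
#' @param cohort a \linkS4class{TrioCohort} with phenotypes.
#' @param pairs analysis pairs (\code{\link{buildPairs}} output, both roles
#'   allowed; the relevant role is selected).
#' @param grm \linkS4class{RelatednessMatrix} covering the pair offspring.
#' @param outcome battery column name (e.g. "sbp").
#' @param score a \linkS4class{ScoreDefinition}.
#' @param exposure,conditioning "maternal", "paternal" or "offspring";
#'   exactly one of the two must be "offspring"-free parental role.
#' @param stratum "all", "20-40" or "40-60" (offspring age at measurement).
#' @param battery optional precomputed battery.
#' @param maxScoreMissing refuse if the exposure or conditioning score is
#'   missing for more than this fraction of pairs (default 0.2).
#' @return one-row data.frame: outcome, score_set, exposure, conditioning,
#'   stratum, n, effect, se, p.
#' @export
fitConditionalGRS <- function(cohort, pairs, grm, outcome, score,
                              exposure = c("maternal", "paternal", "offspring"),
                              conditioning = c("offspring", "maternal", "paternal"),
                              stratum = c("all", "20-40", "40-60"),
                              battery = NULL, maxScoreMissing = 0.2) {
  exposure <- match.arg(exposure)
  conditioning <- match.arg(conditioning)
  stratum <- match.arg(stratum)
  if (exposure == conditioning)
    stop("exposure and conditioning scores must differ")
  parentRole <- setdiff(c(exposure, conditioning), "offspring")
  if (length(parentRole) != 1L)
    stop("exactly one of exposure/conditioning must be a parental score")
  roleMap <- c(maternal = "mother", paternal = "father")
  pr <- roleMap[[parentRole]]
  pp <- pairs[pairs$parent_role == pr, ]
  if (!nrow(pp)) stop("no ", pr, "-offspring pairs available")
  if (is.null(battery)) battery <- preparePhenotypes(cohort)

  grsP <- buildGRS(cohort, score = score, role = pr)
  grsO <- buildGRS(cohort, score = score, role = "offspring")
  gP <- grsP[pp$parent_id]
  gO <- grsO[pp$offspring_id]
  missFrac <- max(mean(is.na(gP)), mean(is.na(gO)))
  if (missFrac > maxScoreMissing)
    stop("score missing for ", round(100 * missFrac), "% of pairs; refusing")

  b <- battery[match(pp$offspring_id, battery$individual_id), ]
  gExp <- if (exposure == "offspring") gO else gP
  gCond <- if (conditioning == "offspring") gO else gP
  d <- data.frame(id = pp$offspring_id, y = b[[outcome]],
                  grs_exposure = gExp, grs_conditioning = gCond,
                  age = b$age, sex = b$sex, occasion = b$occasion)
  if (stratum != "all")
    d <- d[!is.na(d$age) & !is.na(stratifyByAge(d$age)) &
             stratifyByAge(d$age) == stratum, ]
  d <- d[stats::complete.cases(d), ]
  if (nrow(d) < 10L) stop("fewer than 10 complete rows in stratum ", stratum)
  y <- as.numeric(scale(d$y))  # standardized within the analysis sample
  X <- cbind("(Intercept)" = 1, grs_exposure = d$grs_exposure,
             grs_conditioning = d$grs_conditioning,
             .covariateDesign(d$age, d$sex, d$occasion))
  ft <- .fitAndTest(y, X, grm, d$id, "grs_exposure")
  data.frame(outcome = outcome, score_set = score@name,
             exposure = exposure, conditioning = conditioning,
             stratum = stratum, n = nrow(d),
             effect = ft$tests$grs_exposure$effect,
             se = ft$tests$grs_exposure$se,
             p = ft$tests$grs_exposure$p)
}

#' Run the full conditional-score analysis grid
#'
#' Loops \code{\link{fitConditionalGRS}} over outcomes, the three standard
#' score sets and the three exposure|conditioning configurations
#' (maternal|offspring, paternal|offspring, offspring|maternal).
#'
#' @param cohort,pairs,grm as in \code{\link{fitConditionalGRS}}.
#' @param outcomes battery outcome columns.
#' @param scores named list of \linkS4class{ScoreDefinition}s (default the
#'   cohort's standard sets).
#' @param configurations list of c(exposure, conditioning) pairs.
#' @param stratum analysis stratum.
#' @return data.frame with one row per combination.
#' @export
runConditionalAnalyses <- function(cohort, pairs, grm,
                                   outcomes = c("sbp", "dbp", "glucose", "tc",
                                                "ldl", "hdl", "tg", "bmi"),
                                   scores = standardScores(cohort),
                                   configurations = list(
                                     c("maternal", "offspring"),
                                     c("paternal", "offspring"),
                                     c("offspring", "maternal")),
                                   stratum = "all") {
  battery <- preparePhenotypes(cohort)
  rows <- list()
  for (cfg in configurations)
    for (sc in scores)
      for (oc in outcomes)
        rows[[length(rows) + 1L]] <- fitConditionalGRS(
          cohort, pairs, grm, oc, sc, exposure = cfg[1],
          conditioning = cfg[2], stratum = stratum, battery = battery)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Replicate a conditional test over phenotype redraws
#'
#' Calibration engine for type-I error and power studies: the genotyped
#' cohort, pair set and relationship-matrix decomposition stay fixed while
#' phenotypes are redrawn \code{nReps} times from the generative model and
#' the conditional analysis is re-run each time. Conditioning on genotypes
#' this way keeps the per-replicate cost at a rotation and a 1-D profile
#' fit instead of a fresh N x N eigendecomposition.
#'
#' @param cohort a \linkS4class{TrioCohort} with genotypes (phenotypes are
#'   overwritten each replicate).
#' @param config the \code{\link{simConfig}} generating phenotypes.
#' @param pairs,grm fixed pair set and (ideally pre-decomposed over the
#'   analysis offspring) relationship matrix.
#' @param nReps number of replicates.
#' @param outcome,score,exposure,conditioning,stratum passed to
#'   \code{\link{fitConditionalGRS}}.
#' @return data.frame with one row per replicate: effect, se, p, n.
#' @export
replicateConditionalTest <- function(cohort, config, pairs, grm, nReps,
                                     outcome = "sbp", score,
                                     exposure = "maternal",
                                     conditioning = "offspring",
                                     stratum = "all") {
  rows <- vector("list", nReps)
  for (r in seq_len(nReps)) {
    ci <- simulatePhenotypes(cohort, config)
    rows[[r]] <- fitConditionalGRS(ci, pairs, grm, outcome, score,
                                   exposure = exposure,
                                   conditioning = conditioning,
                                   stratum = stratum)[
                                     , c("effect", "se", "p", "n")]
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write an analysis results table
#'
#' Emits the results of an analysis family as a TSV (full precision, so a
#' round-trip read reproduces the stored values exactly) and returns the
#' table invisibly. Empty inputs produce a header-only file with an
#' explanatory comment line.
#'
#' @param results data.frame of results.
#' @param file output path.
#' @return the results, invisibly.
#' @export
resultsTable <- function(results, file) {
  con <- file(file, "w")
  on.exit(close(con))
  if (!nrow(results))
    writeLines("# no analyses in this family (empty stratum or input)", con)
  utils::write.table(format(results, digits = 17, trim = TRUE,
                            scientific = FALSE),
                     con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(results)
}
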