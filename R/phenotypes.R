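#' Prepare blood pressure from repeated readings
#'
#' The working value is the average of the second and third readings; for
#' individuals with only two readings the second is used; fewer than two
#' readings gives missing. Individuals on blood-pressure medication have
#' \code{adjustment} mmHg added after averaging (+15 for systolic, +10 for
#' diastolic), reconstructing an untreated level rather than entering
#' medication as a covariate (which risks collider bias).
#'
#' @param r1,r2,r3 numeric vectors of readings (NA = not taken).
#' @param med logical/0-1 medication-use flag.
#' @param adjustment mmHg added for medicated individuals (15 SBP, 10 DBP).
#' @return numeric vector of prepared values.
#' @export
prepareBP <- function(r1, r2, r3, med, adjustment = 15) {
  n <- length(r1)
  stopifnot(length(r2) == n, length(r3) == n, length(med) == n)
  nRead <- (!is.na(r1)) + (!is.na(r2)) + (!is.na(r3))
  val <- ifelse(!is.na(r2) & !is.na(r3), (r2 + r3) / 2,
                ifelse(!is.na(r2), r2, r3))
  val[nRead < 2] <- NA
  val + ifelse(!is.na(med) & med > 0, adjustment, 0)
}

#' Friedewald LDL cholesterol
#'
#' LDL = TC - HDL - TG / 2.2, all in mmol/L (the 2.2 divisor is the
#' mmol/L form of the triglyceride term). Missing in any input propagates.
#'
#' @param tc,hdl,tg total cholesterol, HDL, triglycerides (mmol/L, raw
#'   scale).
#' @return LDL cholesterol in mmol/L.
#' @export
deriveLDL <- function(tc, hdl, tg) tc - hdl - tg / 2.2

#' Transform and trim an outcome variable
#'
#' Variables tagged non-normal (\code{glucose}, \code{tg}, \code{bmi}) are
#' natural-log transformed first; then values strictly more than
#' \code{nSD} standard deviations from the (post-transform) mean are set
#' missing in a single pass (not iterated). The returned values stay on
#' the analysis scale (log scale for the log-first variables). With fewer
#' than 10 non-missing values the trim is skipped with a warning; zero SD
#' removes nothing.
#'
#' @param x numeric values on the raw scale.
#' @param variable variable name; \code{glucose}, \code{tg}, \code{bmi}
#'   are log-first, all others are treated as normal.
#' @param nSD trim threshold in SD units (default 4).
#' @return numeric vector on the analysis scale, with attribute
#'   \code{logTransformed}.
#' @export
transformAndTrim <- function(x, variable, nSD = 4) {
  logFirst <- variable %in% c("glucose", "tg", "bmi")
  if (logFirst) {
    bad <- !is.na(x) & x <= 0
    if (any(bad)) {
      warning(sum(bad), " nonpositive value(s) of ", variable,
              " set missing before log transform")
      x[bad] <- NA
    }
    x <- log(x)
  }
  ok <- !is.na(x)
  if (sum(ok) < 10L) {
    warning("fewer than 10 non-missing values of ", variable,
            ": outlier trim skipped")
  } else {
    m <- mean(x[ok]); s <- stats::sd(x[ok])
    if (s > 0) x[ok & abs(x - m) > nSD * s] <- NA
  }
  structure(x, logTransformed = logFirst)
}

#' Birth-registry eligibility for the birthweight analyses
#'
#' An offspring is excluded if any of: multiple birth, congenital
#' malformation, induced or caesarean delivery, birthweight under 1000 g,
#' or gestation shorter than 258 days. Missing flags are treated as
#' eligible (the count is reported via the \code{n_missing_flags}
#' attribute).
#'
#' @param ph phenotype data.frame with columns \code{multiple_birth},
#'   \code{malformation}, \code{csection_or_induced},
#'   \code{birthweight_g}, \code{gestation_days}.
#' @return logical eligibility vector.
#' @export
birthweightExclusions <- function(ph) {
  f <- function(x) !is.na(x) & x > 0
  excl <- f(ph$multiple_birth) | f(ph$malformation) |
    f(ph$csection_or_induced) |
    (!is.na(ph$birthweight_g) & ph$birthweight_g < 1000) |
    (!is.na(ph$gestation_days) & ph$gestation_days < 258)
  nMissing <- sum(is.na(ph$multiple_birth) | is.na(ph$malformation) |
                    is.na(ph$csection_or_induced))
  structure(!excl, n_missing_flags = nMissing)
}

#' Age strata for the stratified analyses
#'
#' Half-open strata: ages in [20, 40) fall in "20-40", ages in [40, 60)
#' in "40-60"; everyone else (including over-60s, too few to present) is
#' unstratified (NA).
#'
#' @param age numeric ages at measurement.
#' @return factor with levels "20-40", "40-60".
#' @export
stratifyByAge <- function(age) {
  out <- rep(NA_character_, length(age))
  out[!is.na(age) & age >= 20 & age < 40] <- "20-40"
  out[!is.na(age) & age >= 40 & age < 60] <- "40-60"
  factor(out, levels = c("20-40", "40-60"))
}

#' Build the cleaned offspring phenotype battery
#'
#' Runs the full preparation once per cohort, in the analysis order:
#' blood-pressure averaging with the medication adjustment, BMI from
#' weight/height, Friedewald LDL, then transform-and-trim of every outcome
#' (SBP, DBP, TC, LDL, HDL on the natural scale; glucose, TG, BMI
#' log-first). The trim is applied exactly once, before any model fitting
#' or stratification. Birth-registry eligibility and birthweight in kg are
#' attached where available.
#'
#' @param cohort a \linkS4class{TrioCohort} with phenotypes.
#' @return data.frame (one row per offspring) with columns
#'   \code{individual_id}, \code{sbp}, \code{dbp}, \code{glucose},
#'   \code{tc}, \code{ldl}, \code{hdl}, \code{tg}, \code{bmi} (analysis
#'   scale), \code{age}, \code{sex}, \code{occasion},
#'   \code{birthweight_kg}, \code{bw_eligible}.
#' @export
preparePhenotypes <- function(cohort) {
  ph <- if (is(cohort, "TrioCohort")) cohort@phenotypes else cohort
  if (!nrow(ph)) stop("cohort has no phenotype table")
  sbp <- prepareBP(ph$sbp1, ph$sbp2, ph$sbp3, ph$bp_med, 15)
  dbp <- prepareBP(ph$dbp1, ph$dbp2, ph$dbp3, ph$bp_med, 10)
  bmi <- ph$weight_kg / ph$height_m^2
  ldl <- deriveLDL(ph$tc, ph$hdl, ph$tg)
  out <- data.frame(
    individual_id = ph$individual_id,
    sbp = transformAndTrim(sbp, "sbp"),
    dbp = transformAndTrim(dbp, "dbp"),
    glucose = transformAndTrim(ph$glucose, "glucose"),
    tc = transformAndTrim(ph$tc, "tc"),
    ldl = transformAndTrim(ldl, "ldl"),
    hdl = transformAndTrim(ph$hdl, "hdl"),
    tg = transformAndTrim(ph$tg, "tg"),
    bmi = transformAndTrim(bmi, "bmi"),
    age = ph$age, sex = ph$sex, occasion = ph$occasion,
    birthweight_kg = ph$birthweight_g / 1000,
    bw_eligible = as.logical(birthweightExclusions(ph))
  )
  rownames(out) <- NULL
  out
}
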