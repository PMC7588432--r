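#' Sample-level quality control
#'
#' Removes individuals whose autosomal heterozygosity (fraction of
#' hard-called genotypes equal to 1) lies more than \code{hetSD} standard
#' deviations from the cohort mean, and individuals flagged as
#' sex-mismatched in the pedigree metadata (logical column
#' \code{sex_mismatch}, if present; genetic sex inference needs X-chromosome
#' data and is out of scope). With zero heterozygosity SD (all individuals
#' identical) no one is removed.
#'
#' @param cohort a \linkS4class{TrioCohort}.
#' @param hetSD threshold in SD units (default 5).
#' @return list with elements \code{cohort} (filtered) and \code{report}
#'   (class \code{QCReport}: per-filter removal counts and thresholds).
#' @export
sampleQC <- function(cohort, hetSD = 5) {
  stopifnot(is(cohort, "TrioCohort"))
  G <- rbind(cohort@mothers, cohort@fathers, cohort@offspring)
  if (nrow(G) == 0L) stop("cohort has no genotyped individuals")
  H <- round(G)
  het <- rowMeans(H == 1, na.rm = TRUE)
  m <- mean(het); s <- stats::sd(het)
  badHet <- if (is.na(s) || s == 0) rep(FALSE, length(het))
            else abs(het - m) > hetSD * s
  ped <- cohort@pedigree
  sexSkipped <- !("sex_mismatch" %in% names(ped))
  badSex <- if (sexSkipped) rep(FALSE, nrow(G)) else {
    flag <- ped$sex_mismatch[match(rownames(G), ped$individual_id)]
    !is.na(flag) & flag
  }
  drop <- rownames(G)[badHet | badSex]
  keepRows <- function(mat) mat[!(rownames(mat) %in% drop), , drop = FALSE]
  out <- cohort
  out@mothers <- keepRows(cohort@mothers)
  out@fathers <- keepRows(cohort@fathers)
  out@offspring <- keepRows(cohort@offspring)
  if (nrow(out@mothers) + nrow(out@fathers) + nrow(out@offspring) == 0L)
    stop("sampleQC removed every individual")
  if (nrow(out@phenotypes))
    out@phenotypes <- out@phenotypes[!(out@phenotypes$individual_id %in% drop), ]
  if (nrow(out@latents))
    out@latents <- out@latents[!(out@latents$individual_id %in% drop), ]
  report <- structure(list(
    filter = "sample",
    n_removed_het = sum(badHet), n_removed_sex = sum(badSex),
    n_removed_total = length(drop),
    het_mean = m, het_sd = s, het_sd_threshold = hetSD,
    sex_check_skipped = sexSkipped,
    removed_ids = drop), class = "QCReport")
  list(cohort = out, report = report)
}

#' Variant-level quality control
#'
#' Drops SNPs with minor allele frequency strictly below \code{mafMin} or
#' missing fraction strictly above \code{missMax}, both computed over all
#' genotyped individuals (a SNP at exactly 5.0\% missing is retained; a SNP
#' at MAF exactly 0.005 is retained).
#'
#' @param cohort a \linkS4class{TrioCohort}.
#' @param mafMin minimum minor allele frequency (default 0.005).
#' @param missMax maximum missing fraction (default 0.05).
#' @return list with \code{cohort} and \code{report} as in
#'   \code{\link{sampleQC}}.
#' @export
variantQC <- function(cohort, mafMin = 0.005, missMax = 0.05) {
  stopifnot(is(cohort, "TrioCohort"))
  G <- rbind(cohort@mothers, cohort@fathers, cohort@offspring)
  if (nrow(G) == 0L) stop("cohort has no genotyped individuals")
  p <- colMeans(G, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  missFrac <- colMeans(is.na(G))
  badMAF <- is.na(maf) | maf < mafMin
  badMiss <- missFrac > missMax
  keep <- !(badMAF | badMiss)
  if (!any(keep)) stop("variantQC removed every SNP")
  out <- cohort
  out@mothers <- cohort@mothers[, keep, drop = FALSE]
  out@fathers <- cohort@fathers[, keep, drop = FALSE]
  out@offspring <- cohort@offspring[, keep, drop = FALSE]
  out@snpTable <- cohort@snpTable[keep, , drop = FALSE]
  rownames(out@snpTable) <- NULL
  report <- structure(list(
    filter = "variant",
    n_removed_maf = sum(badMAF), n_removed_missing = sum(badMiss),
    n_removed_total = sum(!keep),
    maf_min = mafMin, miss_max = missMax,
    removed_ids = cohort@snpTable$snp_id[!keep]), class = "QCReport")
  list(cohort = out, report = report)
}

#' @export
print.QCReport <- function(x, ...) {
  cat("QCReport (", x$filter, " filter): removed ", x$n_removed_total,
      "\n", sep = "")
  if (x$filter == "sample") {
    cat("  heterozygosity +/-", x$het_sd_threshold, "SD:", x$n_removed_het,
        "removed (mean", format(x$het_mean, digits = 4),
        "SD", format(x$het_sd, digits = 4), ")\n")
    if (x$sex_check_skipped) cat("  sex check skipped (no metadata)\n")
    else cat("  sex mismatch:", x$n_removed_sex, "removed\n")
  } else {
    cat("  MAF <", x$maf_min, ":", x$n_removed_maf, "; missing >",
        x$miss_max, ":", x$n_removed_missing, "\n")
  }
  invisible(x)
}
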