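#' Construct a ScoreDefinition
#'
#' @param name score set label.
#' @param entries data.frame with \code{snp_id}, \code{bw_increasing_allele}.
#' @return a \linkS4class{ScoreDefinition}.
#' @export
scoreDefinition <- function(name, entries) {
  new("ScoreDefinition", name = name,
      entries = as.data.frame(entries)[, c("snp_id", "bw_increasing_allele")])
}

#' The three standard birthweight score sets of a cohort
#'
#' Derives \code{all_autosomal} (every score SNP), \code{maternal_effect}
#' (SNPs with a maternal effect, including those that also act through the
#' fetal genome) and \code{maternal_only} score definitions from the SNP
#' table's effect classes. For cohorts read from disk the same sets come
#' from \code{score_definitions.tsv}.
#'
#' @param x a \linkS4class{TrioCohort} or its SNP table.
#' @return named list of \linkS4class{ScoreDefinition} objects.
#' @export
standardScores <- function(x) {
  st <- if (is(x, "TrioCohort")) x@snpTable else x
  tab <- .scoreDefTable(st)
  lapply(split(tab, tab$score_name)[c("all_autosomal", "maternal_effect",
                                      "maternal_only")],
         function(d) scoreDefinition(d$score_name[1], d))
}

#' Read score definitions from a TSV
#'
#' @param path a \code{score_definitions.tsv} with columns
#'   \code{score_name}, \code{snp_id}, \code{bw_increasing_allele}.
#' @return named list of \linkS4class{ScoreDefinition} objects.
#' @export
readScoreDefinitions <- function(path) {
  tab <- utils::read.delim(path, sep = "\t")
  lapply(split(tab, tab$score_name), function(d)
    scoreDefinition(d$score_name[1], d))
}

#' Resolve a score definition against a cohort SNP table
#'
#' Entries whose SNP is absent from the table, or whose designated
#' birthweight-increasing allele matches neither recorded allele, are
#' dropped with a message (mirroring scores built on panels where some
#' source SNPs are unavailable).
#'
#' @param score a \linkS4class{ScoreDefinition}.
#' @param st the cohort SNP table.
#' @return the score with unresolvable entries removed.
#' @export
resolveScore <- function(score, st) {
  e <- score@entries
  i <- match(e$snp_id, st$snp_id)
  missing <- is.na(i)
  badAllele <- !missing &
    e$bw_increasing_allele != st$counted_allele[i] &
    e$bw_increasing_allele != st$other_allele[i]
  drop <- missing | badAllele
  if (any(drop))
    message("score '", score@name, "': dropped ", sum(drop),
            " unresolvable entr", if (sum(drop) == 1) "y" else "ies",
            " (", sum(missing), " absent, ", sum(badAllele),
            " allele mismatch)")
  scoreDefinition(score@name, e[!drop, , drop = FALSE])
}

#' Build an unweighted genetic risk score
#'
#' Per individual, the sum over the score SNPs of the dosage of the
#' birthweight-increasing allele: the stored counted-allele dosage d where
#' the counted allele is the increasing one, 2 - d where it is the
#' decreasing one. Missing dosages are imputed to twice the sample
#' frequency of the increasing allele (computed in the supplied matrix);
#' individuals missing more than \code{maxMissing} of the score SNPs get
#' \code{NA} with a warning.
#'
#' @param G dosage matrix (rows = individuals) or a
#'   \linkS4class{TrioCohort} with \code{role}.
#' @param st the cohort SNP table (ignored when \code{G} is a cohort).
#' @param score a \linkS4class{ScoreDefinition} (resolved internally).
#' @param role family role when \code{G} is a cohort.
#' @param maxMissing maximum tolerated missing fraction per individual.
#' @return named numeric score vector with attribute \code{n_snps_used}.
#' @export
buildGRS <- function(G, st, score, role = c("offspring", "mother", "father"),
                     maxMissing = 0.1) {
  if (is(G, "TrioCohort")) {
    role <- match.arg(role)
    st <- G@snpTable
    G <- dosages(G, role)
  }
  stopifnot(is.matrix(G), is(score, "ScoreDefinition"))
  score <- resolveScore(score, st)
  e <- score@entries
  if (nrow(e) == 0L) stop("score '", score@name, "' has no resolvable SNPs")
  i <- match(e$snp_id, st$snp_id)
  s <- ifelse(e$bw_increasing_allele == st$counted_allele[i], 1, -1)
  d <- G[, i, drop = FALSE]
  d[, s < 0] <- 2 - d[, s < 0, drop = FALSE]
  pInc <- colMeans(d, na.rm = TRUE) / 2
  missFrac <- rowMeans(is.na(d))
  d <- .imputeTo(d, 2 * pInc)
  sc <- rowSums(d)
  tooMissing <- missFrac > maxMissing
  if (any(tooMissing)) {
    warning(sum(tooMissing), " individual(s) missing > ",
            round(100 * maxMissing), "% of score SNPs: score set NA")
    sc[tooMissing] <- NA
  }
  structure(sc, names = rownames(G), n_snps_used = nrow(e))
}
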