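#' Write a trio cohort to plain-text files
#'
#' Emits, under \code{dir}: \code{pedigree.tsv}, \code{phenotypes.tsv},
#' \code{snp_table.tsv}, \code{score_definitions.tsv} (the three standard
#' score sets derived from the SNP effect classes), and the dosages either
#' as \code{dosages.tsv} (rows = individuals, first column
#' \code{individual_id}, remaining columns one per SNP; missing = empty
#' cell) or as \code{cohort.vcf} (VCF 4.2, one sample per individual, ALT =
#' counted allele, FORMAT \code{DS}; missing = "."). The files round-trip
#' losslessly through \code{\link{readCohort}}.
#'
#' @param cohort a \linkS4class{TrioCohort}.
#' @param dir output directory (created if absent).
#' @param format "tsv" (default) or "vcf".
#' @return invisibly, the vector of files written.
#' @export
writeCohort <- function(cohort, dir, format = c("tsv", "vcf")) {
  format <- match.arg(format)
  stopifnot(is(cohort, "TrioCohort"))
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
    stop("cannot create directory ", dir)
  wt <- function(df, f) utils::write.table(
    df, file.path(dir, f), sep = "\t", quote = FALSE,
    row.names = FALSE, na = "")
  wt(cohort@pedigree, "pedigree.tsv")
  if (nrow(cohort@phenotypes)) wt(cohort@phenotypes, "phenotypes.tsv")
  wt(cohort@snpTable, "snp_table.tsv")
  sdef <- .scoreDefTable(cohort@snpTable)
  if (is.null(sdef))
    sdef <- data.frame(score_name = character(), snp_id = character(),
                       bw_increasing_allele = character())
  wt(sdef, "score_definitions.tsv")
  files <- c("pedigree.tsv",
             if (nrow(cohort@phenotypes)) "phenotypes.tsv",
             "snp_table.tsv", "score_definitions.tsv")
  G <- rbind(cohort@mothers, cohort@fathers, cohort@offspring)
  if (format == "tsv") {
    d <- data.frame(individual_id = rownames(G), G, check.names = FALSE)
    wt(d, "dosages.tsv")
    files <- c(files, "dosages.tsv")
  } else {
    .writeVcfDS(G, cohort@snpTable, file.path(dir, "cohort.vcf"))
    files <- c(files, "cohort.vcf")
  }
  invisible(file.path(dir, files))
}

.scoreDefTable <- function(st) {
  sets <- list(
    all_autosomal = st$effect_class %in% c("maternal_only", "both", "fetal_only"),
    maternal_effect = st$effect_class %in% c("maternal_only", "both"),
    maternal_only = st$effect_class == "maternal_only")
  do.call(rbind, lapply(names(sets), function(nm) {
    i <- which(sets[[nm]])
    if (!length(i)) return(NULL)
    data.frame(score_name = nm, snp_id = st$snp_id[i],
               bw_increasing_allele = st$bw_increasing_allele[i])
  }))
}

## Fixed-format VCF 4.2 emission (serialization only; reading goes through
## VariantAnnotation). DS counts the ALT (= counted) allele.
.writeVcfDS <- function(G, st, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=TrioMR",
    '##FORMAT=<ID=DS,Number=1,Type=Float,Description="Counted-allele dosage">',
    paste0("##contig=<ID=", sort(unique(st$chromosome)), ">"),
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", rownames(G)), collapse = "\t")), con)
  ds <- t(G)  # SNPs x samples
  body <- vapply(seq_len(nrow(st)), function(i) {
    v <- ds[i, ]
    v <- ifelse(is.na(v), ".", formatC(v, format = "g", digits = 10))
    paste(c(st$chromosome[i], st$position[i], st$snp_id[i],
            st$other_allele[i], st$counted_allele[i], ".", "PASS", ".",
            "DS", v), collapse = "\t")
  }, "")
  writeLines(body, con)
}

#' Read a trio cohort written by \code{writeCohort}
#'
#' Reconstructs a \linkS4class{TrioCohort} from a cohort directory,
#' auto-detecting the dosage format (\code{dosages.tsv} or
#' \code{cohort.vcf}; the VCF path uses \pkg{VariantAnnotation}).
#' Simulation latents are not persisted and come back empty.
#'
#' @param dir cohort directory.
#' @return a \linkS4class{TrioCohort}.
#' @export
readCohort <- function(dir) {
  rt <- function(f, ...) utils::read.delim(file.path(dir, f), sep = "\t",
                                           na.strings = "", ...)
  ped <- rt("pedigree.tsv")
  st <- rt("snp_table.tsv",
           colClasses = c(snp_id = "character", counted_allele = "character",
                          other_allele = "character",
                          bw_increasing_allele = "character"))
  phFile <- file.path(dir, "phenotypes.tsv")
  ph <- if (file.exists(phFile) && file.size(phFile) > 0)
    rt("phenotypes.tsv") else data.frame()
  if (file.exists(file.path(dir, "dosages.tsv"))) {
    d <- rt("dosages.tsv", check.names = FALSE)
    G <- as.matrix(d[, -1, drop = FALSE])
    rownames(G) <- d$individual_id
  } else if (file.exists(file.path(dir, "cohort.vcf"))) {
    G <- .readVcfDS(file.path(dir, "cohort.vcf"), st)
  } else stop("no dosages.tsv or cohort.vcf under ", dir)
  if (!identical(colnames(G), st$snp_id))
    G <- G[, st$snp_id, drop = FALSE]
  pick <- function(role) {
    ids <- ped$individual_id[ped$role == role]
    G[intersect(rownames(G), ids), , drop = FALSE]
  }
  new("TrioCohort", mothers = pick("mother"), fathers = pick("father"),
      offspring = pick("offspring"), snpTable = st, pedigree = ped,
      phenotypes = ph, latents = data.frame())
}

.readVcfDS <- function(path, st) {
  if (!requireNamespace("VariantAnnotation", quietly = TRUE))
    stop("reading VCF cohorts requires the VariantAnnotation package")
  vcf <- VariantAnnotation::readVcf(path)
  ds <- VariantAnnotation::geno(vcf)$DS
  G <- t(ds)  # samples x SNPs
  colnames(G) <- rownames(ds)
  G[, st$snp_id, drop = FALSE]
}
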