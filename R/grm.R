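#' Exclusion mask around score SNPs
#'
#' Returns the SNP ids usable for the relationship matrix: every SNP whose
#' distance to each same-chromosome score SNP strictly exceeds
#' \code{windowBP} (a SNP at exactly the window distance is excluded, as is
#' every score SNP itself). SNPs on chromosomes carrying no score SNP are
#' always retained. This keeps association signal in the fixed effects from
#' being re-absorbed by the random-effect relationship structure.
#'
#' @param st cohort SNP table with \code{snp_id}, \code{chromosome},
#'   \code{position}.
#' @param scoreSnpIds character vector of score SNP ids.
#' @param windowBP exclusion window in base pairs (default 1e6 = 1 Mb).
#' @return character vector of retained SNP ids.
#' @export
exclusionMask <- function(st, scoreSnpIds, windowBP = 1e6) {
  sc <- st[st$snp_id %in% scoreSnpIds, c("chromosome", "position")]
  keep <- rep(TRUE, nrow(st))
  keep[st$snp_id %in% scoreSnpIds] <- FALSE
  for (ch in unique(sc$chromosome)) {
    onCh <- which(st$chromosome == ch & keep)
    if (!length(onCh)) next
    d <- outer(st$position[onCh], sc$position[sc$chromosome == ch],
               function(a, b) abs(a - b))
    keep[onCh[apply(d <= windowBP, 1L, any)]] <- FALSE
  }
  st$snp_id[keep]
}

#' Build a GCTA-style genetic relationship matrix
#'
#' A_jk = (1/m) * sum_i (x_ij - 2 p_i)(x_ik - 2 p_i) / (2 p_i (1 - p_i)),
#' with p_i the sample counted-allele frequency; the same standardized
#' product is used on the diagonal. Missing dosages are mean-imputed to
#' 2 p_i before standardization; monomorphic SNPs are skipped.
#'
#' @param G dosage matrix (rows = individuals), typically the offspring of
#'   the analysis pair set restricted to the \code{\link{exclusionMask}}
#'   SNPs.
#' @param lowRank if \code{TRUE}, keep the (scaled) standardized genotype
#'   matrix Z with A = Z Z' / m instead of materializing A; the spectral
#'   decomposition then runs through an SVD of Z (rank <= m), which is much
#'   cheaper than an N x N eigendecomposition when m << N and gives
#'   identical mixed-model results.
#' @return a \linkS4class{RelatednessMatrix}.
#' @export
buildGRM <- function(G, lowRank = FALSE) {
  stopifnot(is.matrix(G), nrow(G) >= 1L)
  p <- colMeans(G, na.rm = TRUE) / 2
  poly <- !is.na(p) & p > 0 & p < 1
  if (sum(poly) == 0L) stop("no polymorphic SNPs left for the GRM")
  if (sum(poly) < 2L) warning("GRM built from a single SNP")
  G <- G[, poly, drop = FALSE]
  p <- p[poly]
  if (is.null(rownames(G)))
    rownames(G) <- sprintf("sample%04d", seq_len(nrow(G)))
  G <- .imputeTo(G, 2 * p)
  Z <- sweep(sweep(G, 2, 2 * p), 2, sqrt(2 * p * (1 - p)), "/")
  if (lowRank) {
    return(new("RelatednessMatrix", Z = Z / sqrt(ncol(Z)),
               sampleIds = rownames(G), m = ncol(Z)))
  }
  A <- tcrossprod(Z) / ncol(Z)
  A <- (A + t(A)) / 2
  new("RelatednessMatrix", A = A, sampleIds = rownames(G), m = ncol(Z))
}

#' @describeIn eigenDecompose Spectral decomposition A = U diag(d) U' with
#'   eigenvalues in decreasing order; eigenvalues below -1e-8 raise a
#'   warning and all negative eigenvalues are clamped to zero (the matrix
#'   is PSD up to sampling noise). Errors on non-symmetric input. In the
#'   low-rank representation only the k = rank nonzero eigenpairs are
#'   computed, via the SVD of Z; the remaining eigenvalues are implicitly
#'   zero.
#' @export
setMethod("eigenDecompose", "RelatednessMatrix", function(x, ...) {
  if (nrow(x@A) == 0L) {  # low-rank representation
    sv <- svd(x@Z, nv = 0)
    keep <- sv$d > sv$d[1] * 1e-12
    x@eigenU <- sv$u[, keep, drop = FALSE]
    x@eigenValues <- sv$d[keep]^2
    return(x)
  }
  A <- x@A
  if (max(abs(A - t(A))) > 1e-8) stop("relationship matrix is not symmetric")
  e <- eigen(A, symmetric = TRUE)
  if (any(e$values < -1e-8))
    warning("negative eigenvalues clamped to zero (min ",
            format(min(e$values), digits = 3), ")")
  x@eigenU <- e$vectors
  x@eigenValues <- pmax(e$values, 0)
  x
})

#' Subset a relationship matrix to a sample set
#'
#' Reorders/subsets A to \code{ids} (decomposition is dropped and must be
#' redone on the subset).
#'
#' @param x a \linkS4class{RelatednessMatrix}.
#' @param ids individual ids, all present in \code{sampleIds(x)}.
#' @return a \linkS4class{RelatednessMatrix} over \code{ids}.
#' @export
subsetGRM <- function(x, ids) {
  i <- match(ids, x@sampleIds)
  if (anyNA(i)) stop("ids not all present in the relationship matrix")
  if (nrow(x@A) == 0L)
    return(new("RelatednessMatrix", Z = x@Z[i, , drop = FALSE],
               sampleIds = ids, m = x@m))
  new("RelatednessMatrix", A = x@A[i, i, drop = FALSE], sampleIds = ids,
      m = x@m)
}
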