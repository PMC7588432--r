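#' Accessors for TrioMR classes
#'
#' Small accessor family: \code{dosages} returns a dosage matrix for one
#' family role; \code{snpTable}, \code{pedigree}, \code{phenotypes} and
#' \code{latentValues} return the corresponding tables; \code{grmMatrix},
#' \code{sampleIds}, \code{eigenVectors}, \code{eigenValues} expose the
#' relationship matrix and its decomposition; \code{fixedEffects},
#' \code{stdErrors} and \code{varComponents} expose a mixed-model fit.
#'
#' @param x an object of the documented class.
#' @param role one of "mother", "father", "offspring".
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("dosages", function(x, role = c("offspring", "mother", "father"))
  standardGeneric("dosages"))

#' @rdname accessors
#' @export
setGeneric("snpTable", function(x) standardGeneric("snpTable"))

#' @rdname accessors
#' @export
setGeneric("pedigree", function(x) standardGeneric("pedigree"))

#' @rdname accessors
#' @export
setGeneric("phenotypes", function(x) standardGeneric("phenotypes"))

#' @rdname accessors
#' @export
setGeneric("latentValues", function(x) standardGeneric("latentValues"))

#' @rdname accessors
#' @export
setGeneric("grmMatrix", function(x) standardGeneric("grmMatrix"))

#' @rdname accessors
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' @rdname accessors
#' @export
setGeneric("eigenVectors", function(x) standardGeneric("eigenVectors"))

#' @rdname accessors
#' @export
setGeneric("eigenValues", function(x) standardGeneric("eigenValues"))

#' @rdname accessors
#' @export
setGeneric("fixedEffects", function(x) standardGeneric("fixedEffects"))

#' @rdname accessors
#' @export
setGeneric("stdErrors", function(x) standardGeneric("stdErrors"))

#' @rdname accessors
#' @export
setGeneric("varComponents", function(x) standardGeneric("varComponents"))

#' Spectral decomposition of a relationship matrix
#'
#' @param x a \linkS4class{RelatednessMatrix}.
#' @param ... passed to methods.
#' @export
setGeneric("eigenDecompose", function(x, ...) standardGeneric("eigenDecompose"))

setMethod("dosages", "TrioCohort", function(x, role = c("offspring", "mother", "father")) {
  role <- match.arg(role)
  slot(x, c(offspring = "offspring", mother = "mothers",
            father = "fathers")[[role]])
})

setMethod("snpTable", "TrioCohort", function(x) x@snpTable)
setMethod("pedigree", "TrioCohort", function(x) x@pedigree)
setMethod("phenotypes", "TrioCohort", function(x) x@phenotypes)
setMethod("latentValues", "TrioCohort", function(x) x@latents)

setMethod("grmMatrix", "RelatednessMatrix", function(x) {
  if (nrow(x@A) == 0L && nrow(x@Z) > 0L) {
    A <- tcrossprod(x@Z)  # Z is pre-scaled by 1/sqrt(m)
    dimnames(A) <- list(x@sampleIds, x@sampleIds)
    return(A)
  }
  x@A
})
setMethod("sampleIds", "RelatednessMatrix", function(x) x@sampleIds)
setMethod("eigenVectors", "RelatednessMatrix", function(x) {
  if (!length(x@eigenValues)) stop("not decomposed; call eigenDecompose() first")
  x@eigenU
})
setMethod("eigenValues", "RelatednessMatrix", function(x) {
  if (!length(x@eigenValues)) stop("not decomposed; call eigenDecompose() first")
  x@eigenValues
})

setMethod("fixedEffects", "LMMFit", function(x) x@beta)
setMethod("stdErrors", "LMMFit", function(x) x@se)
setMethod("varComponents", "LMMFit",
          function(x) c(sigma_g2 = x@sigmaG2, sigma_e2 = x@sigmaE2))

#' @export
setMethod("logLik", "LMMFit", function(object, ...) {
  structure(object@loglik, df = length(object@beta) + 2L,
            nobs = object@n, class = "logLik")
})

#' @export
setMethod("coef", "LMMFit", function(object, ...) object@beta)

setMethod("show", "TrioCohort", function(object) {
  ped <- object@pedigree
  cat("TrioCohort:", length(unique(ped$family_id)), "families;",
      nrow(object@mothers), "mothers,", nrow(object@fathers), "fathers,",
      nrow(object@offspring), "offspring;", nrow(object@snpTable), "SNPs\n")
  cls <- table(object@snpTable$effect_class)
  cat("  SNP classes:", paste(names(cls), cls, sep = "=", collapse = ", "), "\n")
  cat("  phenotypes:", nrow(object@phenotypes), "rows",
      if (nrow(object@latents)) "(simulation latents attached)" else "", "\n")
})

setMethod("show", "ScoreDefinition", function(object) {
  cat("ScoreDefinition '", object@name, "': ", nrow(object@entries),
      " SNPs\n", sep = "")
})

setMethod("show", "RelatednessMatrix", function(object) {
  lowRank <- nrow(object@A) == 0L
  cat("RelatednessMatrix:", length(object@sampleIds),
      "individuals, built from", object@m, "SNPs",
      if (lowRank) "(low-rank representation)" else "", ";",
      if (length(object@eigenValues)) "decomposed" else "not decomposed", "\n")
})

setMethod("show", "LMMFit", function(object) {
  cat("Two-variance-component FIML fit (n =", object@n, ")\n")
  est <- cbind(estimate = object@beta, se = object@se)
  print(round(est, 5))
  cat("sigma_g2 =", format(object@sigmaG2, digits = 5),
      " sigma_e2 =", format(object@sigmaE2, digits = 5),
      " logLik =", format(object@loglik, digits = 8), "\n")
  if (length(object@notes)) cat("notes:", paste(object@notes, collapse = "; "), "\n")
})

setMethod("show", "LRTResult", function(object) {
  cat("LRT: chi-square =", format(object@stat, digits = 5),
      "df =", object@df, "p =", format.pval(object@p, digits = 4), "\n")
})

setMethod("show", "PathModel", function(object) {
  cat("PathModel: gamma =", object@gamma, " lambda1 =", object@lambda1,
      " lambda2 =", object@lambda2, " theta =", object@theta, "\n")
  cat("  birthweight variance from maternal GRS:",
      object@gamma^2 * object@lambda1^2, "\n")
  cat("  outcome variance from maternal GRS:   ",
      outcomeVarianceExplained(object), "\n")
  cat("  implied birthweight-outcome correlation:",
      impliedBWOutcomeCorrelation(object), "\n")
})
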