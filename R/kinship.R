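#' KING-robust kinship estimation from genotypes
#'
#' Estimates pairwise kinship from hard-called genotypes (dosages rounded
#' to 0/1/2) with the KING-robust estimator in its symmetric-denominator
#' form: kinship = (N_het,het - 2 N_opposite_hom) / (N_het(i) + N_het(j)),
#' all counts taken over the SNPs non-missing in both individuals; the
#' opposite-homozygote fraction IBS0 = N_opposite_hom / N_overlap separates
#' parent-offspring pairs (IBS0 ~ 0) from full siblings within the
#' first-degree band. Duplicates estimate at ~0.5, first-degree relatives
#' at ~0.25, unrelated pairs at ~0.
#'
#' @param x a \linkS4class{TrioCohort} (all genotyped individuals pooled)
#'   or a dosage matrix (rows = individuals).
#' @param pairs optional two-column data.frame/matrix of (id1, id2) to
#'   restrict the output; default all unordered pairs.
#' @param minOverlap minimum number of jointly non-missing SNPs; pairs
#'   below it are flagged \code{unestimable} (kinship NA).
#' @param minKinship optional floor: only pairs with estimated kinship at
#'   or above it (plus unestimable pairs) are returned, mirroring kinship
#'   tools that report related pairs only; keeps all-pairs scans over
#'   thousands of individuals from materializing millions of unrelated
#'   rows.
#' @return data.frame with columns \code{id1}, \code{id2}, \code{kinship},
#'   \code{ibs0_fraction}, \code{n_overlap}, \code{unestimable}.
#' @export
kingKinship <- function(x, pairs = NULL, minOverlap = 50L,
                        minKinship = NULL) {
  G <- if (is(x, "TrioCohort")) rbind(x@mothers, x@fathers, x@offspring) else x
  stopifnot(is.matrix(G), nrow(G) >= 2L)
  H <- round(G)
  Mna <- !is.na(H)
  Het <- (H == 1) & Mna
  Hom0 <- (H == 0) & Mna
  Hom2 <- (H == 2) & Mna
  storage.mode(Het) <- storage.mode(Hom0) <- storage.mode(Hom2) <- "double"
  storage.mode(Mna) <- "double"
  ids <- rownames(G)
  if (!is.null(pairs)) {
    ## per-pair path: elementwise counts, no N x N intermediates
    pairs <- as.matrix(pairs)
    i1 <- match(pairs[, 1], ids); i2 <- match(pairs[, 2], ids)
    if (anyNA(i1) || anyNA(i2)) stop("pairs contain unknown individual ids")
    pc <- function(A, B) rowSums(A[i1, , drop = FALSE] * B[i2, , drop = FALSE])
    nhh <- pc(Het, Het)
    nopp <- pc(Hom0, Hom2) + pc(Hom2, Hom0)
    denom <- pc(Het, Mna) + pc(Mna, Het)
    nov <- pc(Mna, Mna)
    bad <- nov < minOverlap
    res <- data.frame(
      id1 = ids[i1], id2 = ids[i2],
      kinship = ifelse(bad, NA_real_, (nhh - 2 * nopp) / denom),
      ibs0_fraction = ifelse(bad, NA_real_, nopp / nov),
      n_overlap = as.integer(nov), unestimable = bad)
    rownames(res) <- NULL
    return(res)
  }
  Nhh <- tcrossprod(Het)
  Nopp <- tcrossprod(Hom0, Hom2)
  Nopp <- Nopp + t(Nopp)
  NhetInOv <- tcrossprod(Het, Mna)   # [i,j] = het SNPs of i non-missing in j
  Nov <- tcrossprod(Mna)
  denom <- NhetInOv + t(NhetInOv)
  kin <- (Nhh - 2 * Nopp) / denom
  ibs0 <- Nopp / Nov

  sel <- upper.tri(kin)
  if (!is.null(minKinship))
    sel <- sel & (Nov < minOverlap | (!is.na(kin) & kin >= minKinship))
  idx <- which(sel, arr.ind = TRUE)
  ov <- Nov[idx]
  bad <- ov < minOverlap
  res <- data.frame(
    id1 = ids[idx[, 1]], id2 = ids[idx[, 2]],
    kinship = ifelse(bad, NA_real_, kin[idx]),
    ibs0_fraction = ifelse(bad, NA_real_, ibs0[idx]),
    n_overlap = as.integer(ov),
    unestimable = bad)
  rownames(res) <- NULL
  res
}

#' Classify pairwise relationships from kinship estimates
#'
#' Applies the 2^(-3/2)-spaced degree cutoffs recommended with the
#' KING-robust estimator: kinship > 0.354 duplicate; (0.177, 0.354] first
#' degree; (0.0884, 0.177] second; (0.0442, 0.0884] third; otherwise
#' unrelated. First-degree pairs split into \code{parent_offspring}
#' (IBS0 fraction < \code{ibs0Split}) versus \code{full_sibling}.
#'
#' @param kin data.frame from \code{\link{kingKinship}}.
#' @param ibs0Split IBS0 cutoff within the first-degree band (default 0.005).
#' @return the input with a \code{degree} factor column added.
#' @export
classifyRelationship <- function(kin, ibs0Split = 0.005) {
  stopifnot(all(c("kinship", "ibs0_fraction") %in% names(kin)))
  k <- kin$kinship
  degree <- rep(NA_character_, length(k))
  ok <- !is.na(k)
  degree[ok & k > 0.354] <- "duplicate"
  first <- ok & k > 0.177 & k <= 0.354
  degree[first & kin$ibs0_fraction < ibs0Split] <- "parent_offspring"
  degree[first & kin$ibs0_fraction >= ibs0Split] <- "full_sibling"
  degree[ok & k > 0.0884 & k <= 0.177] <- "second"
  degree[ok & k > 0.0442 & k <= 0.0884] <- "third"
  degree[ok & k <= 0.0442] <- "unrelated"
  kin$degree <- factor(degree, levels = c("duplicate", "parent_offspring",
                                          "full_sibling", "second", "third",
                                          "unrelated"))
  kin
}

#' Build the parent-offspring analysis pair sets
#'
#' From classified \code{parent_offspring} relationships and pedigree birth
#' years: the older member of each pair is assigned the parent role; pairs
#' with a birth-year gap of \code{maxGapExcl} years or fewer are removed
#' (gap 16 is the first retained value at the default), as are pairs with
#' equal birth years (parent role undecidable) or a missing birth year
#' (with a warning). The parent's pedigree sex splits the result into
#' mother-offspring and father-offspring sets; a parent may appear in
#' several pairs (one per offspring), an offspring at most once per parent
#' role (highest-kinship pair kept).
#'
#' @param relationships output of \code{\link{classifyRelationship}}.
#' @param ped pedigree data.frame with \code{individual_id}, \code{sex},
#'   \code{birth_year}.
#' @param maxGapExcl pairs with gap <= this many years are removed
#'   (default 15).
#' @return data.frame with columns \code{parent_id}, \code{offspring_id},
#'   \code{parent_role} ("mother"/"father"), \code{birth_year_gap},
#'   \code{kinship}.
#' @export
buildPairs <- function(relationships, ped, maxGapExcl = 15) {
  stopifnot("degree" %in% names(relationships))
  po <- relationships[!is.na(relationships$degree) &
                        relationships$degree == "parent_offspring", ]
  if (nrow(po) == 0L)
    return(data.frame(parent_id = character(), offspring_id = character(),
                      parent_role = character(), birth_year_gap = integer(),
                      kinship = numeric()))
  by1 <- ped$birth_year[match(po$id1, ped$individual_id)]
  by2 <- ped$birth_year[match(po$id2, ped$individual_id)]
  noBY <- is.na(by1) | is.na(by2)
  if (any(noBY)) {
    warning(sum(noBY), " parent-offspring pair(s) excluded: missing birth year")
    po <- po[!noBY, ]; by1 <- by1[!noBY]; by2 <- by2[!noBY]
  }
  tie <- by1 == by2
  po <- po[!tie, ]; by1c <- by1[!tie]; by2c <- by2[!tie]
  older1 <- by1c < by2c
  parent <- ifelse(older1, po$id1, po$id2)
  offspring <- ifelse(older1, po$id2, po$id1)
  gap <- abs(by1c - by2c)
  keep <- gap > maxGapExcl
  parent <- parent[keep]; offspring <- offspring[keep]; gap <- gap[keep]
  kin <- po$kinship[keep]
  sexP <- ped$sex[match(parent, ped$individual_id)]
  out <- data.frame(parent_id = parent, offspring_id = offspring,
                    parent_role = ifelse(sexP == "F", "mother", "father"),
                    birth_year_gap = as.integer(gap), kinship = kin)
  ## one parent per role per offspring: keep the highest-kinship pair
  out <- out[order(out$offspring_id, out$parent_role, -out$kinship), ]
  dup <- duplicated(out[, c("offspring_id", "parent_role")])
  out <- out[!dup, ]
  rownames(out) <- NULL
  out
}
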