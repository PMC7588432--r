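# Shared kinship fixture: 80 families at 10,000 unlinked SNPs.
kinCohort <- local({
  value <- NULL
  function() {
    if (is.null(value)) {
      cfg <- simConfig(nFamilies = 80L,
                       nScoreSNPs = c(maternal_only = 0L, both = 0L,
                                      fetal_only = 0L),
                       nBackgroundSNPs = 10000L, polygenicH2 = 0, gamma = 0,
                       dosageMissingRate = 0.002, seed = 404)
      value <<- simulateGenotypes(cfg)
    }
    value
  }
})

test_that("duplicate genotypes estimate kinship 0.5 with zero IBS0", {
  set.seed(2)
  g <- rbinom(2000, 2, 0.4)
  G <- rbind(a = g, b = g, c = rbinom(2000, 2, 0.4))
  colnames(G) <- sprintf("s%d", 1:2000)
  k <- kingKinship(G, pairs = data.frame(id1 = "a", id2 = "b"))
  expect_equal(k$kinship, 0.5)
  expect_equal(k$ibs0_fraction, 0)
})

test_that("kinship concentrates at 0.25 for parent-offspring, 0 for unrelated", {
  co <- kinCohort()
  kin <- kingKinship(co)
  po <- truePOPairs(co)
  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  kin$key <- key(kin$id1, kin$id2)
  kPO <- kin$kinship[kin$key %in% key(po$id1, po$id2)]
  expect_equal(length(kPO), nrow(po))
  expect_lt(abs(mean(kPO) - 0.25), 0.01)
  ped <- pedigree(co)
  fam <- ped$family_id[match(kin$id1, ped$individual_id)] ==
    ped$family_id[match(kin$id2, ped$individual_id)]
  expect_lt(abs(mean(kin$kinship[!fam])), 0.005)
  # parent-offspring pairs share an allele everywhere: IBS0 ~ 0
  expect_lt(mean(kin$ibs0_fraction[kin$key %in% key(po$id1, po$id2)]), 1e-3)
})

test_that("the kinship estimator is symmetric in the pair", {
  co <- kinCohort()
  ids <- rownames(dosages(co, "offspring"))[1:6]
  p12 <- data.frame(id1 = ids[c(1, 3, 5)], id2 = ids[c(2, 4, 6)])
  p21 <- data.frame(id1 = p12$id2, id2 = p12$id1)
  k12 <- kingKinship(co, pairs = p12)
  k21 <- kingKinship(co, pairs = p21)
  expect_equal(k12$kinship, k21$kinship)
  expect_equal(k12$ibs0_fraction, k21$ibs0_fraction)
})

test_that("pairs below the overlap minimum are flagged unestimable", {
  G <- rbind(a = c(1, 1, rep(NA, 98)), b = c(1, 1, rep(NA, 98)),
             c = rep(1, 100))
  colnames(G) <- sprintf("s%d", 1:100)
  k <- kingKinship(G, pairs = data.frame(id1 = "a", id2 = "b"),
                   minOverlap = 50L)
  expect_true(k$unestimable)
  expect_true(is.na(k$kinship))
})

test_that("relationship classes follow the published threshold bands", {
  mk <- function(kin, ibs0) data.frame(kinship = kin, ibs0_fraction = ibs0)
  expect_equal(as.character(classifyRelationship(mk(0.25, 0.0005))$degree),
               "parent_offspring")
  expect_equal(as.character(classifyRelationship(mk(0.25, 0.04))$degree),
               "full_sibling")
  expect_equal(as.character(classifyRelationship(mk(0.01, 0.06))$degree),
               "unrelated")
  expect_equal(as.character(classifyRelationship(mk(0.45, 0))$degree),
               "duplicate")
  expect_equal(as.character(classifyRelationship(mk(0.12, 0.03))$degree),
               "second")
  expect_equal(as.character(classifyRelationship(mk(0.05, 0.05))$degree),
               "third")
})

test_that("classification recovers >=99% of true first-degree pairs", {
  co <- kinCohort()
  rel <- classifyRelationship(kingKinship(co))
  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  rel$key <- key(rel$id1, rel$id2)
  po <- truePOPairs(co); sib <- trueSibPairs(co)
  poHit <- rel$degree[match(key(po$id1, po$id2), rel$key)] == "parent_offspring"
  expect_gte(mean(poHit), 0.99)
  if (!is.null(sib) && nrow(sib)) {
    sibHit <- rel$degree[match(key(sib$id1, sib$id2), rel$key)] == "full_sibling"
    expect_gte(mean(sibHit), 0.99)
  }
})

test_that("pair construction applies the 15-year rule and role logic", {
  rel <- data.frame(id1 = c("p1", "p2", "p3", "k4", "p5", "p5", "p5"),
                    id2 = c("k1", "k2", "k3", "p4", "k5", "k6", "k7"),
                    kinship = 0.25, ibs0_fraction = 0,
                    degree = factor("parent_offspring",
                                    levels = c("duplicate", "parent_offspring",
                                               "full_sibling", "second",
                                               "third", "unrelated")))
  ped <- data.frame(
    individual_id = c("p1", "k1", "p2", "k2", "p3", "k3", "p4", "k4",
                      "p5", "k5", "k6", "k7"),
    sex = c("F", "F", "F", "M", "M", "F", "F", "M",
            "F", "F", "M", "F"),
    birth_year = c(1960, 1975,   # gap 15 -> removed
                   1960, 1976,   # gap 16 -> retained
                   1960, 1960,   # tie -> removed
                   1950, 1980,   # offspring listed as id1; p4 is the parent
                   1950, 1975, 1978, 1980))  # one mother, three offspring
  pairs <- buildPairs(rel, ped)
  expect_false("k1" %in% pairs$offspring_id)
  expect_true("k2" %in% pairs$offspring_id)
  expect_false("k3" %in% pairs$offspring_id)
  r4 <- pairs[pairs$offspring_id == "k4", ]
  expect_equal(r4$parent_id, "p4")
  expect_equal(r4$parent_role, "mother")
  expect_equal(sum(pairs$parent_id == "p5"), 3)
  expect_true(all(pairs$birth_year_gap > 15))
})

test_that("pairs with missing birth years are excluded with a warning", {
  rel <- data.frame(id1 = "p1", id2 = "k1", kinship = 0.25,
                    ibs0_fraction = 0,
                    degree = factor("parent_offspring",
                                    levels = c("duplicate", "parent_offspring",
                                               "full_sibling", "second",
                                               "third", "unrelated")))
  ped <- data.frame(individual_id = c("p1", "k1"), sex = c("F", "F"),
                    birth_year = c(NA, 1980))
  expect_warning(pairs <- buildPairs(rel, ped), "birth year")
  expect_equal(nrow(pairs), 0)
})

test_that("the per-pair kinship path matches the all-pairs path", {
  co <- kinCohort()
  kAll <- kingKinship(co)
  set.seed(6)
  pp <- kAll[sample(nrow(kAll), 50), c("id1", "id2")]
  kp <- kingKinship(co, pairs = pp)
  m <- match(paste(kp$id1, kp$id2), paste(kAll$id1, kAll$id2))
  expect_identical(kp$kinship, kAll$kinship[m])
  expect_identical(kp$ibs0_fraction, kAll$ibs0_fraction[m])
  expect_identical(kp$n_overlap, kAll$n_overlap[m])
  # the kinship floor only drops sub-threshold rows
  kf <- kingKinship(co, minKinship = 0.04)
  expect_true(all(kf$kinship >= 0.04 | kf$unestimable))
  expect_gte(nrow(kAll[!is.na(kAll$kinship) & kAll$kinship >= 0.04, ]),
             nrow(kf[!kf$unestimable, ]))
})
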