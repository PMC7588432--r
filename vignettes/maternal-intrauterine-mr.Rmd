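---
title: "Family-based Mendelian randomization of maternal intrauterine effects: models and methods"
author: "TrioMR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Family-based Mendelian randomization of maternal intrauterine effects: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The scientific question

The Developmental Origins of Health and Disease (DOHaD) hypothesis holds
that an adverse intrauterine environment restricts fetal growth and raises
the offspring's later-life cardiometabolic risk. Observationally, lower
birthweight is associated with higher adult blood pressure, adverse lipid
profiles and glucose levels — but that association could equally arise from
genetic pleiotropy: fetal alleles that lower birthweight and raise
cardiometabolic risk through the same physiology (the fetal insulin
hypothesis), or from shared environment.

Family-based Mendelian randomization separates these explanations. The
maternal alleles of birthweight-associated SNPs influence the intrauterine
environment; the half of them not transmitted to the child can affect the
child's outcomes *only* through that environment (given the assumptions
below). Conditional on the offspring's own genetic risk score (GRS), an
association between the **maternal** GRS and an offspring cardiometabolic
outcome therefore supports an intrauterine mechanism, while an association
of the **offspring** GRS conditional on the maternal one indicates direct
fetal genetic effects. A **paternal** GRS, which has no intrauterine
channel, serves as a negative control for postnatal (dynastic) mechanisms.

`TrioMR` implements this analysis end to end: a generative simulator for
genotyped mother–father–offspring cohorts, genotype QC and kinship-based
pair construction, unweighted birthweight GRSs and a genetic relationship
matrix (GRM), a two-variance-component mixed model fitted by full
information maximum likelihood (FIML) through a spectral rotation,
conditional association analyses, and analytic power / path-model
calculators.

# The path model

All variables are standardized to unit variance. A single latent
intrauterine factor $U$ mediates the maternal genetic effect:

$$U = \gamma\, z(\mathrm{GRS}_m) + e_u, \qquad \mathrm{var}(e_u) = 1 - \gamma^2$$
$$\mathrm{BW} = \lambda_1 U + \text{(fetal effects)} + \varepsilon_{bw}$$
$$Y = \lambda_2 U + \text{(fetal pleiotropy)} + \text{(polygenic)} + \varepsilon_{y},
  \qquad \mathrm{cov}(\varepsilon_{bw}, \varepsilon_y) = \Theta$$

Consequences used throughout the package and its tests:

* birthweight variance explained by the maternal GRS is $\gamma^2\lambda_1^2$
  (`gammaFromBWVariance()` inverts this);
* outcome variance explained by the maternal GRS is $\gamma^2\lambda_2^2$
  (`outcomeVarianceExplained()`);
* the implied birthweight–outcome correlation is $\lambda_1\lambda_2 + \Theta$
  (`impliedBWOutcomeCorrelation()`).

The model assumes no direct causal arrow from birthweight to the outcome
and no maternal-genotype path other than the intrauterine factor (no
postnatal/dynastic maternal effect). With the illustrative values
$\lambda_1 = -0.5$, $\lambda_2 = 0.1$ and a maternal GRS explaining 0.5% of
birthweight variance, $\gamma = \sqrt{0.005/\lambda_1^2} = 0.1414$ and the
maternal GRS explains only 0.02% of outcome variance — the central reason
power matters so much in this design.

```{r}
library(TrioMR)
pathModel(gamma = 0.1414, lambda1 = -0.5, lambda2 = 0.1, theta = 0)
```

# Analytic power for conditional score tests

The conditional test regresses the outcome on the tested (parental) score
while adjusting for a score correlated $r$ with it (parent–offspring GRS
correlation is 0.5 under random mating). Conditioning inflates the variance
of the tested coefficient by $1/(1-r^2)$, so for a score explaining a
marginal fraction $q^2$ of outcome variance in $n$ pairs the test statistic
is noncentral $\chi^2_1$ with

$$\mathrm{ncp} = n\, q^2 (1 - r^2),$$

and power is the mass beyond the central $\chi^2_1$ critical value at
$\alpha$ (`powerConditionalGRS()`; `minDetectableVariance()` inverts it by
bisection to a relative tolerance of $10^{-8}$). This deflation model
reproduces every published power figure of the study design it follows
(80%/68% at $q^2 = 0.04\%$ for 26,057 and 19,792 pairs; 79%/67% at the
slightly reduced per-outcome sample sizes; $\ge 80\%$ and $> 66\%$ at
$q^2 = 0.09\%$ in the age strata) — validated in the acceptance suite, not
assumed. A Monte-Carlo oracle (`powerBySimulation()`) cross-checks the
closed form on a grid.

# The generative simulator

`simConfig()` + `simulateTrioCohort()` generate a genotyped cohort with the
exact structure the analysis assumes, so every downstream stage is testable
without restricted data.

* **Genotypes.** Unlinked autosomal SNPs (linkage is irrelevant to the
  tested quantities, as the real scores use independent genome-wide
  significant loci); parental dosages Binomial(2, p) under random mating;
  offspring receive one allele from each parent (heterozygotes transmit
  the counted allele with probability 1/2). Sibships (1–8 offspring per
  family, truncated-geometric by default — the source design states only
  the 1–8 range) induce the cryptic relatedness the mixed model absorbs.
  Genotype missingness is injected after transmission.
* **SNP classes.** `maternal_only` (31), `both` (40) and `fetal_only`
  (133) score SNPs — giving the standard score sets of 204 (all), 71
  (maternal effect) and 31 (maternal-only) — plus `background` SNPs that
  carry the polygenic outcome component and feed the GRM. Building the
  polygenic term from real background SNPs (rather than a family-structured
  normal) means GRM estimation is exercised end to end. Per-SNP effects
  give equal standardized contributions within a class; the score
  orientation (`bw_increasing_allele`) is randomized against the stored
  counted allele so orientation handling is always exercised. With the
  illustrative $\lambda_1 < 0$ the oriented score's net association with
  simulated birthweight is negative — the latent factor is a
  growth-restricting exposure; only sign products are identifiable.
* **Phenotypes.** The latent outcome is written onto systolic blood
  pressure (the trait the age-stratified analyses focus on) with three
  readings around the latent level (reading SD 3 mmHg; 12% of individuals
  have only two readings); medicated individuals' stored readings are their
  on-treatment values, so the +15/+10 mmHg reconstruction rule downstream
  is genuinely exercised. Diastolic BP and the blood chemistry carry
  partial loadings on the same latent outcome; glucose, triglycerides and
  BMI are lognormal. Trait locations and scales are realistic adult
  Norwegian survey values. Birth-registry fields (birthweight in grams,
  gestation length, delivery/malformation/multiple-birth flags), cell-wise
  missingness and rare gross outliers complete the raw table.
* **Determinism.** One seed drives a single generator consumed in a
  documented order; a fixed seed reproduces the cohort, and its on-disk
  files, bit-identically.

What the simulator does **not** emulate: linkage disequilibrium,
X-chromosome transmission, genotyping error, imputation uncertainty,
population stratification, assortative mating, or medication use that is
correlated with blood pressure. Passing tests therefore demonstrate the
pipeline's statistical behaviour under the stated model, not robustness to
those real-data complications.

# QC, kinship and analysis pairs

`sampleQC()` removes individuals with hard-called heterozygosity beyond ±5
SD of the cohort mean and honors an externally supplied sex-mismatch flag
(genetic sex inference needs X data and is out of scope). `variantQC()`
drops SNPs with MAF < 0.005 or missingness > 5%, both bounds strict as
stated. `kingKinship()` implements the KING-robust estimator in its
symmetric-denominator form,

$$\hat\phi_{ij} = \frac{N^{het,het}_{ij} - 2 N^{opp}_{ij}}
                       {N^{het}_i + N^{het}_j},$$

on hard-called genotypes over the SNPs non-missing in both individuals
(association analyses keep dosages). Degrees use the $2^{-3/2}$-spaced
cutoffs recommended with that estimator (first degree: kinship in
(0.177, 0.354]); within first degree, parent–offspring pairs are split from
full siblings at an opposite-homozygote fraction of 0.005 —
parent–offspring pairs share an allele at every locus, so their IBS0 is
essentially zero with error-free genotypes. `buildPairs()` assigns the
older member as parent, removes pairs with a birth-year gap of 15 years or
less (ties in birth year are excluded outright), and splits
mother–offspring from father–offspring sets by the parent's pedigree sex.

# Scores, GRM and the rotated FIML mixed model

GRSs are **unweighted** sums of birthweight-increasing allele dosages
(weighting by observed birthweight effects would presume the wrong
estimand when the exposure is growth restriction); missing dosages are
mean-imputed at twice the in-sample increasing-allele frequency, and an
individual missing more than 10% of a score's SNPs gets a missing score.

The GRM uses the GCTA-style standardized product
$A_{jk} = m^{-1}\sum_i (x_{ij}-2p_i)(x_{ik}-2p_i)/(2p_i(1-p_i))$ with
in-sample frequencies, the same form on the diagonal, monomorphic SNPs
skipped, and score SNPs plus everything within 1 Mb of them excluded — so
association signal in the fixed effects is not re-absorbed by the random
effect.

The mixed model is $y \sim N(X\beta,\; A\sigma_g^2 + I\sigma_e^2)$ — exactly
two variance components, one of them an uncorrelated residual. Writing
$A = U\,\mathrm{diag}(d)\,U'$ and rotating ($y^* = U'y$, $X^* = U'X$) makes
the observations independent with variances $v_i = d_i\sigma_g^2 +
\sigma_e^2$, so FIML reduces to a one-dimensional profile search over the
variance ratio: given $\sigma_g^2/\sigma_e^2$, $\beta$ is weighted least
squares and $\sigma_e^2$ has a closed form. `fitFIML()` searches
$\log(\sigma_g^2/\sigma_e^2)$ on a coarse grid over $[-15, 15]$ refined by
golden-section, and evaluates the $\sigma_g^2 = 0$ boundary (ordinary least
squares) explicitly. ML rather than REML is used because likelihoods are
compared across fixed-effect specifications; p-values come from
likelihood-ratio tests (`lrt()`), two-sided as $\chi^2_1$, with Wald
standard errors reported alongside.

Numerical notes, all deliberate:

* The bounded ratio search matters: a GRM standardized with in-sample
  frequencies annihilates the ones vector exactly, and with an intercept in
  the design the ML likelihood acquires an improper ridge as the ratio
  grows ($\sigma_e^2$ collapsing on a perfectly fitted coordinate).
  Solutions at the upper search edge are flagged as non-converged.
* When $A \propto I$ the variance split is unidentifiable; the fit reports
  the total variance as residual and says so in its notes.
* Eigenvalues below $-10^{-8}$ warn and are clamped to zero; eigenvector
  sign and ordering cannot affect any reported statistic (tested).
* A **low-rank path** (`buildGRM(..., lowRank = TRUE)`) keeps the scaled
  standardized genotype matrix $Z$ (with $A = ZZ'$) and decomposes by SVD;
  the zero-eigenvalue null space enters the likelihood through Gram-matrix
  complements, so results are identical to the dense path (tested to
  $10^{-10}$) while avoiding the $N \times N$ eigendecomposition when the
  GRM is built from fewer SNPs than individuals.
* Rows with missing outcome or covariates are dropped listwise before the
  GRM is subset and decomposed, once per analysis sample.

# Phenotype preparation and the analysis families

`preparePhenotypes()` applies, exactly once and in this order: blood
pressure as the mean of readings 2 and 3 (the second reading alone when
only two were taken), +15/+10 mmHg added for medicated individuals after
averaging (a covariate for medication would invite collider bias); BMI from
weight and height; Friedewald LDL = TC − HDL − TG/2.2 in mmol/L (no
high-TG suppression is applied, since none is stated for the source
protocol); then, for every outcome, a single-pass trim of values more than
4 SD from the mean, computed after natural-log transformation for the
non-normal variables (glucose, TG, BMI) and in the analysis sample. Trimmed
variables stay on their analysis (log) scale. Birth-registry eligibility
excludes multiple births, congenital malformations, induced or caesarean
deliveries, birthweight under 1000 g and gestation under 258 days; missing
flags count as eligible and are tallied.

Three analysis families run through the same mixed model:

* `fitPhenotypicBWModel()`: outcome ~ birthweight (kg) + birthweight² +
  age + sex + occasion on registry-eligible offspring (at least 100), with
  LRT p-values for the linear and quadratic terms;
* `fitConditionalGRS()` / `runConditionalAnalyses()`: z-scored outcome ~
  exposure GRS + conditioning GRS + age + sex + occasion for the three
  score sets and the three configurations maternal|offspring,
  paternal|offspring, offspring|maternal — effects in standardized outcome
  units per allele, scores kept on the allele-count scale;
* age strata [20, 40) and [40, 60), half-open (the prose "under 40" wins
  over inclusive table labels), over-60s not analyzed separately.

No multiple-testing correction is applied anywhere, matching the source
protocol's reporting. The outcome is standardized within each analysis
sample; doubling its raw scale provably changes nothing.

# Study designs used in the acceptance suite

Problem sizes were chosen to make each check sharp at a sensible cost: the
trio-correlation check uses 10,000 single-offspring trios at 100 SNPs
(Monte-Carlo SE of the correlation ≈ 0.0075); rotation equivalence uses
N = 50 against a direct multivariate-normal oracle and a brute-force
generic optimizer; the calibration studies use ~2,000 mother–offspring
pairs per replicate, 500 replicates for the type-I study and 250 for the
recovery/power study.

Two design points deserve emphasis:

* **Replicates redraw genotypes.** Holding genotypes fixed and redrawing
  phenotypes is tempting (it amortizes the eigendecomposition) but wrong
  for calibration: each fixed cohort carries a realized, nonzero partial
  association between the maternal score and the fixed pleiotropic and
  polygenic components, which phenotype-only replicates then detect
  repeatedly — we measured a "type-I error" of ~0.11 under that shortcut
  versus ~0.05 (well-calibrated) with fresh cohorts. The low-rank FIML path
  is what makes 500 fresh end-to-end replicates affordable.
  `replicateConditionalTest()` (phenotype redraws on a fixed cohort)
  remains available for effect-recovery exercises, with this caveat.
* **The power-validation scenario omits the background polygenic
  component.** The analytic calculator models a residual uncorrelated
  across individuals. When substantial polygenic variance is present, the
  mixed model absorbs it and is *more* powerful than the calculator
  predicts (we measured ≈ +0.03–0.05 at power ≈ 0.8); matching the
  calculator is therefore checked in the setting it models, with the mixed
  model still fitted (its genetic component estimating ≈ 0). The type-I
  study keeps the polygenic background, where the mixed model must absorb
  it for the standard errors to be honest.

In the calibration studies kinship runs in verification mode over
pedigree-candidate pairs (per-pair counting); full all-pairs discovery is
validated separately (unit tests recover ≥ 99% of true first-degree pairs
at 10,000 SNPs).

# Known limitations

* The simulator's medication indicator is independent of true blood
  pressure, so the +15/+10 rule is exercised mechanically but not its
  epidemiological consequences.
* The KING-robust estimator is implemented for autosomes with error-free
  hard calls; the IBS0 parent–offspring/sibling split (0.005) would need
  re-tuning for genotypes with appreciable error rates.
* With GRMs built from a few hundred SNPs, variance-component estimates
  are attenuated by GRM noise; the pipeline's inferential targets (fixed
  effects and their LRTs) are insensitive to this, but $\sigma_g^2$ itself
  should not be interpreted as a heritability estimate at small SNP
  counts.
* Formal instrumental-variable effect estimation is out of scope; the
  package tests the presence of maternal genetic effects, it does not
  size a causal effect of the intrauterine environment.
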