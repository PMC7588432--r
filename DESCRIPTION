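Package: TrioMR
Title: Family-Based Mendelian Randomization of Maternal Intrauterine
    Effects with Genetic Risk Scores and Eigen-Rotated Mixed Models
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for family-based Mendelian randomization studies of
    intrauterine (maternal genetic) effects on offspring cardiometabolic
    risk. Simulates genotyped mother-father-offspring cohorts under an
    explicit path model linking maternal birthweight-associated alleles, a
    latent intrauterine factor, offspring birthweight and a later-life
    outcome; infers relationships from genotypes with a KING-robust kinship
    estimator and builds parent-offspring analysis pairs; constructs
    unweighted birthweight genetic risk scores and a GCTA-style genetic
    relationship matrix with 1 Mb exclusion zones around score loci; fits a
    two-variance-component linear mixed model by full-information maximum
    likelihood through the spectral rotation of the relationship matrix,
    with likelihood-ratio tests; prepares raw survey phenotypes (blood
    pressure averaging and medication adjustment, Friedewald LDL,
    log-then-trim cleaning, birth-registry exclusions); and provides
    analytic power and path-model variance-decomposition calculators for
    conditional parent/offspring score tests.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports: methods, stats, utils
Suggests: testthat (>= 3.0.0), VariantAnnotation, jsonlite, withr
Config/testthat/edition: 3
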