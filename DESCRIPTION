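Package: microgwas
Title: Metagenome Genome-Wide Association Analysis of Host-Associated Microbiomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested, reusable pipeline for metagenome genome-wide association
    studies (M-GWAS) linking host genetic variation to microbial community
    features. Covers variant and feature quality control, alpha/beta diversity
    and ordination, greedy decorrelation of highly correlated microbial
    features, prevalence-dispatched association testing (linear models on
    log-abundance for core taxa, logistic presence/absence models otherwise),
    multivariate Pillai-trace MANOVA genotype-beta-diversity scans, LD-based
    locus clumping, distance-based redundancy analysis with adjusted R-squared,
    forward selection and a permutation null for genotype-explained
    beta-diversity variance, Fisher-exact PheWAS enrichment, and bidirectional
    one-sample Mendelian randomization via unweighted genetic risk scores and
    two-stage least squares. Includes a synthetic genotype-microbiome-trait
    cohort generator with planted effects for parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR,
    vegan
Suggests:
    ape,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
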