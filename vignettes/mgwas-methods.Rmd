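---
title: "Methods: microbiome GWAS, variance partitioning and Mendelian randomization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: microbiome GWAS, variance partitioning and Mendelian randomization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(microgwas)
library(dplyr)
```

## The problem

A metagenome genome-wide association study (M-GWAS) asks how much of the
person-to-person variation in a host-associated microbial community — here
modelled on a nasal microbiome cohort — is attributable to host genetic
variation, and whether individual variants shape individual taxa or
pathways. The statistical machinery is a chain: variant and feature quality
control, community diversity and ordination, decorrelation of redundant
microbial features, per-feature association scans, multivariate tests on
community composition, variance partitioning with a permutation null, and
finally one-sample Mendelian randomization (MR) to orient observational
taxon-trait correlations causally. `microgwas` implements that chain as
composable, tibble-returning functions plus `run_pipeline()`.

## The association models

**Prevalence dispatch.** Relative abundances of host-associated taxa are
zero-inflated. Features present in more than 95% of samples ("core", AB
channel) are tested on `log10` relative abundance; features present in
10–95% of samples (PA channel) are dichotomized to presence/absence and
tested with logistic regression, which sidesteps the zero inflation
entirely. Features at or below 10% prevalence, or with mean relative
abundance at or below `1e-4`, are removed beforehand (`feature_qc()`, strict
inequalities).

**AB channel.** `residualize_log_abundance()` regresses
`log10(abundance)` once on the covariate roster (age, sex, BMI, sequencing
read count, top ten host genetic PCs) and the zero-mean residuals are then
regressed on each variant's ALT-dosage separately (`linear_assoc()`). This
two-stage scheme is faster than a per-variant multiple regression and
differs from it only in the residual degrees of freedom (n − 2 instead of
n − 2 − #covariates); at the cohort sizes involved the difference is
negligible, and `diversity_gwas()` — used for the Shannon/Simpson indices
and the community axes — fits the covariates in-model with the exact df.
Zeros in AB features (at most 5% of samples by construction) are floored at
half the smallest nonzero value of that feature before the log; the same
pseudocount rule is used everywhere a log of a possibly-zero abundance is
needed.

**PA channel.** `logistic_assoc()` fits presence on
`[1, dosage, covariates]` by IRLS and reports the Wald z-test on the dosage
coefficient. Non-convergence and (quasi-)separation are reported as flagged
missing results, never exceptions, so a genome-wide scan is never aborted by
one pathological variant.

**Beta-diversity MANOVA.** `manova_beta_gwas()` regresses the top ten
principal coordinates jointly on `[1, dosage, covariates]` and tests the
dosage term with Pillai's trace `V = tr(H(H + E)^{-1})` and its standard F
approximation. Because the hypothesis has one degree of freedom, `H` is
rank-one and `V` reduces to a quadratic form in the covariate-residualized
coordinates, which makes the scan a few matrix products per cohort rather
than per variant — the property the permutation null below depends on. The
implementation is checked against `stats::manova()` in the tests.

**Multiplicity.** `lambda_gc()` (median association chi-square over 0.4549)
diagnoses inflation per feature; `clump_loci()` groups significant variants
into loci greedily by ascending p, with membership requiring both distance
< 1 Mb and dosage r² ≥ 0.2 by default (the complement of the independence
rule "distance < 1 Mb and r² < 0.2"; an `"or"` rule is available);
`bonferroni_threshold()` gives the study-wide threshold, e.g.
5e-8 / 293 ≈ 1.71e-10 for 293 independent features.

## Feature decorrelation

`greedy_representatives()` builds a graph on the features with an edge
wherever |Spearman rho| > 0.995 and repeatedly keeps the highest-degree
node (seeded random tie-break), removing it and its neighbours, recomputing
degrees each round. The kept set is an independent set and a dominating
set: no two kept features are mutually redundant, and every discarded
feature has a kept representative it is correlated with. Rank correlations
are computed on raw relative abundances with zeros included; Spearman is
invariant to monotone transforms, so the log/pseudocount question does not
arise here. The edge statistic is configurable (`abs_rho`, signed `rho`, or
`rho2`) because descriptions of this procedure vary between |rho| and rho².

## Variance partitioning and the permutation null

`dbrda_r2()` embeds a Bray–Curtis matrix by principal coordinates
(positive-eigenvalue axes only; negative eigenvalues are reported but
excluded, with no Lingoes/Cailliez correction — matching the default of the
`capscale`-style analysis this mirrors), regresses the axes on the
predictors and reports explained inertia with the Ezekiel adjustment
`1 − (1 − R²)(n − 1)/(n − p − 1)`. `forward_select()` adds predictors
greedily under three guards: the adjusted R² must strictly increase, the
entry must pass a residual-permutation test (the candidate's fit gain
against row permutations of the current model's residual axes), and the
cumulative adjusted R² must not exceed the all-candidates ceiling. That
ceiling (the `ordiR2step` convention) is itself estimated with error: when
most candidates are pure noise, the ceiling and a single genuine
predictor's adjusted R² estimate the same quantity, and entry is blocked
about half the time — we verified the reference implementation behaves
identically. The guard is therefore a documented toggle (`r2_scope`),
on by default.

`snp_variance_permutation_null()` estimates how much beta-diversity
variance the top genotype loci explain, and calibrates it: scan all
variants by MANOVA, clump to the top `n_top` loci, forward-select the lead
dosages, and take the cumulative adjusted R². Each of the `n_perm`
permutations reassigns whole species profiles to individuals (a row
permutation of the abundance table; the genotype matrix is untouched, which
the function asserts by checksum) and re-runs the same
scan-clump-select pipeline, so the selection optimism is identical under
the null and the empirical p — the fraction of permutations with explained
variance at least the observed — is honest. The inclusive fraction matches
the usual wording of such procedures; the `(k+1)/(n+1)` estimator is a
flag. A one-sample t-test p of the permuted values against the observed is
also emitted: with 100 permutations the empirical fraction cannot go below
0.01, and analysts sometimes quote the t-based tail instead; the two answer
different questions and both are reported rather than reconciled.

One practical caveat surfaced by the synthetic cohorts: with any residual
population structure, genotype and composition are genuinely coupled, so
the scan covariates must include the host PCs — otherwise the "null"
pipeline correctly detects structure and the permutation p concentrates
near zero. The examples and acceptance checks adjust for the top ten PCs
throughout, as the GWAS roster prescribes.

## Mendelian randomization

For a feature-trait pair, `select_instruments()` keeps variants with
exposure-GWAS p < 1e-6, clumps them at r² < 0.1 within 1 Mb, and orients
each so its effect allele increases the exposure. `grs()` sums the oriented
allele counts (an unweighted score). `tsls()` is two-stage least squares
with the covariate roster (age, sex, read count, top ten PCs) in both
stages; the standard error uses the proper TSLS residual — outcome minus
the stage-2 coefficients applied to the *observed* exposure — rather than
the naive stage-2 OLS residual, and the partial F of the score and the
exposure variance explained are reported, with a flag (never a silent
refusal) when F < 10. `bidirectional_mr()` runs both causal directions;
AB-channel exposures enter as `log10` abundance and PA-channel exposures as
the 0/1 presence indicator in a linear-probability first stage (how a
dichotomous exposure should enter TSLS is genuinely underdetermined; this
choice is simple, standard, and prominently documented). Instruments are
selected on the same sample used for estimation, as one-sample MR designs
do; the winner's-curse caveat applies and is not corrected.

## The synthetic cohort generator

The generator exists so every claim above is testable with known truth; its
defaults are fixed once and mirror the cohort the design targets.

* **Genotypes** (`simulate_genotypes()`): Balding–Nichols two-subpopulation
  model, F_ST = 0.01 by default (a mild north/south-style structure whose
  top PC separates the groups), ancestral MAF uniform on (0.05, 0.5),
  binomial genotypes so HWE holds within subpopulation by construction.
  Variants sit every 10 kb on one chromosome so distance-window clumping is
  exercised.
* **Covariates** (`simulate_covariates()`): age ~ N(30, 5), sex ~
  Bernoulli(0.63), BMI ~ N(22, 3), read count ~ log-normal — the cohort
  profile (mean age 30, 63% female) with conventional values where nothing
  is stated.
* **Microbiome** (`simulate_microbiome()`): a hurdle model per taxon —
  latent Gaussian log-abundance (baseline spread, small covariate loadings,
  a per-taxon subpopulation shift, planted AB effects per ALT allele,
  optional confounder loading, noise SD 1) gated by an independent presence
  indicator whose log-odds carry the planted PA effects. About 30% of taxa
  target 98% prevalence (AB channel) and the rest span 15–90% (PA channel);
  surviving values are closed to sum to one.
* **Traits** (`simulate_traits()`): linear in `log10` abundance of the
  causal taxa plus a shared latent confounder `U ~ N(0,1)` loading on both
  the taxon's latent abundance and the trait, so the naive regression is
  biased while the planted SNPs remain valid instruments (no direct
  SNP-trait path).

What the generator does **not** emulate: taxonomic correlation structure
beyond planted blocks, sequencing-depth-dependent detection, phylogenetic
relatedness among taxa, linkage disequilibrium beyond subpopulation
structure, and non-Gaussian trait tails. Passing tests therefore certify
the statistical engine — calibration, recovery, coverage — under the
assumed data-generating process, not the biology of any real cohort.

Closure (dividing by the row sum) attenuates planted per-taxon effects in a
composition-dependent way, so recovery tests estimate the attenuation
empirically across replicates instead of assuming the latent coefficient.

## Numerical and design choices

* Shannon is in natural log units, Simpson is the Gini–Simpson form
  `1 − Σp²` (the conventions of the `vegan` functions used underneath).
* PCoA/PCA axis signs are fixed by making the largest-magnitude loading
  positive, so runs are reproducible.
* HWE uses the exact conditional test (probability-mass rule, no mid-p);
  its null distribution is discrete, so tests assert calibration at
  nominal levels rather than continuous uniformity.
* Missing hard-call dosages are mean-imputed per variant after QC and
  flagged.
* "Over 10%" / "over 1e-4" feature filters are strict inequalities
  (141 of 1401 samples = 10.06% passes).
* LD r² is the squared Pearson correlation of dosages (composite LD; no
  phasing).
* The Fisher enrichment test reports the sample odds ratio `ad/bc`, with a
  zero margin giving p = 1 and a missing OR.
* The observational trait-microbe scan defaults to four host PCs in its
  covariate roster (screening convention) while the GWAS roster uses ten;
  both are arguments, not constants.
* Problem sizes in the tests and the acceptance script — e.g. the n = 500 /
  5,000-variant calibration cohort, 20 recovery replicates, 100 MR
  replicates, 100 permutations at n = 400 — were chosen as the smallest
  sizes at which the binomial noise of the assessed rates is well inside
  the asserted bands.

## Known limitations

* The PA-channel Wald test can be conservative for very rare presence
  patterns; a likelihood-ratio variant is not currently implemented.
* `run_pipeline()` wires GWAS, clumping, variance partitioning and the
  observational scan; full batch MR across all scan-significant pairs is
  left to the user-level functions, since instrument GWAS for many traits
  is the dominant cost and is better scheduled explicitly.
* One-sample MR here has no pleiotropy-robust estimators (Egger, weighted
  median); the design assumes instruments act on the exposure only, which
  the generator guarantees but real data do not.
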