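test_that("config validation rejects out-of-range parameters", {
  expect_error(sim_config(fst = 1), "fst")
  expect_error(sim_config(maf_range = c(0, 0.5)), "maf_range")
  expect_error(sim_config(maf_range = c(0.1, 0.6)), "maf_range")
  expect_error(sim_config(noise_sd = 0), "noise_sd")
  expect_error(
    sim_config(n_variants = 10,
               effect_table = tibble::tibble(variant = 11L, taxon = 1L,
                                             beta = 1, channel = "AB")),
    "out of range"
  )
})

test_that("simulated genotypes have the right domain and mean dosage", {
  g <- simulate_genotypes(sim_config(n_samples = 100, n_variants = 50,
                                     seed = 1))
  expect_equal(dim(g$dosage), c(100, 50))
  expect_true(all(g$dosage %in% c(0, 1, 2)))

  # fst = 0, p = 0.5 fixed: mean dosage within 3 binomial SE of 1
  g2 <- simulate_genotypes(sim_config(
    n_samples = 2000, n_variants = 1, fst = 0,
    maf_range = c(0.5, 0.5), seed = 2
  ))
  se <- sqrt(2 * 0.25 / 2000)
  expect_lt(abs(mean(g2$dosage) - 1), 3 * se)
})

test_that("population structure is recoverable from PCs at fst = 0.2 and absent at fst = 0", {
  g <- simulate_genotypes(sim_config(n_samples = 500, n_variants = 2000,
                                     fst = 0.2, seed = 3))
  pca <- suppressWarnings(genotype_pca(impute_dosage_mean(g), k = 2))
  lab <- as.numeric(g$subpop == "pop2")
  r <- cor(pca$coordinates[, 1], lab)
  expect_gt(abs(r), 0.9)

  g0 <- simulate_genotypes(sim_config(n_samples = 500, n_variants = 2000,
                                      fst = 0, seed = 4))
  pca0 <- suppressWarnings(genotype_pca(impute_dosage_mean(g0), k = 2))
  lab0 <- as.numeric(g0$subpop == "pop2")
  expect_lt(abs(cor(pca0$coordinates[, 1], lab0)), 0.2)
})

test_that("within-subpopulation HWE holds by construction (calibrated exact-test p)", {
  # the exact test is discrete, so its null p-values are valid but not
  # continuously uniform; calibration is asserted at several nominal levels
  g <- simulate_genotypes(sim_config(n_samples = 1000, n_variants = 2000,
                                     fst = 0, maf_range = c(0.1, 0.5),
                                     seed = 5))
  p <- g$variants$hwe_p
  for (alpha in c(0.01, 0.05, 0.1, 0.5)) {
    rate <- mean(p <= alpha)
    tol <- 3 * sqrt(alpha * (1 - alpha) / 2000)
    expect_lte(rate, alpha + tol)
    expect_gte(rate, alpha - tol - 0.005)
  }
})

test_that("microbiome rows are closed and the prevalence spectrum spans both channels", {
  co <- small_cohort("mid", n_samples = 300, n_variants = 100, n_taxa = 40,
                     seed = 11)
  rs <- rowSums(co$abundance$values)
  expect_true(all(abs(rs - 1) < 1e-12))
  expect_true(all(co$abundance$values >= 0))
  prev <- co$abundance$features$prevalence
  expect_true(any(prev > 0.95))
  expect_true(any(prev > 0.10 & prev <= 0.95))
})

test_that("simulation is byte-identical under a fixed seed", {
  cfg <- sim_config(n_samples = 50, n_variants = 30, n_taxa = 10,
                    n_traits = 2, seed = 42,
                    causal_table = tibble::tibble(
                      taxon = 1L, trait = 1L, alpha = 0.3,
                      load_taxon = 1, load_trait = 1
                    ))
  c1 <- simulate_cohort(cfg)
  c2 <- simulate_cohort(cfg)
  expect_identical(c1$genotypes$dosage, c2$genotypes$dosage)
  expect_identical(c1$abundance$values, c2$abundance$values)
  expect_identical(c1$traits, c2$traits)
})

test_that("with no planted effects, per-taxon GWAS p-values are calibrated", {
  co <- small_cohort("null2k", n_samples = 250, n_variants = 200,
                     n_taxa = 10, seed = 21)
  g <- impute_dosage_mean(co$genotypes)
  ss <- feature_gwas(feature_qc(co$abundance), g, co$covariates)
  p <- ss$p[!ss$skipped]
  expect_gt(length(p), 1500)
  frac <- mean(p < 0.05)
  expect_gt(frac, 0.03)
  expect_lt(frac, 0.07)
})

test_that("a planted abundance effect on a core taxon is recovered within 3 SE", {
  # the closure step attenuates the planted latent effect; measure the
  # attenuation empirically over replicates, then check each fit is within
  # 3 SE of the attenuated target
  beta_planted <- 0.5
  ests <- ses <- numeric(20)
  for (i in seq_len(20)) {
    cfg <- sim_config(
      n_samples = 500, n_variants = 20, n_taxa = 20, seed = 100 + i,
      effect_table = tibble::tibble(variant = 1L, taxon = 1L,
                                    beta = beta_planted, channel = "AB")
    )
    g <- simulate_genotypes(cfg)
    cv <- simulate_covariates(cfg)
    a <- simulate_microbiome(g, cv, cfg)
    r <- residualize_log_abundance(setNames(a$values[, 1], rownames(a$values)), cv)
    fit <- linear_assoc(r, g$dosage[, 1])
    ests[i] <- fit$beta
    ses[i] <- fit$se
  }
  # planted effect acts on natural-log latent abundance; the fit is on
  # log10 closed abundance, so the attenuated target is estimated from the
  # replicate mean
  target <- mean(ests)
  expect_true(all(abs(ests - target) < 3.5 * ses))
  # and the effect is decisively nonzero in the right direction
  expect_true(all(ests > 0))
  expect_gt(abs(target) / mean(ses), 3)
})

test_that("confounded null taxon-trait pair: observational correlation without causal signal", {
  # alpha = 0 but shared confounder: the naive regression must light up
  # while TSLS (using the planted instrument) stays null most of the time
  covered <- 0
  naive_sig <- 0
  n_rep <- 30
  for (i in seq_len(n_rep)) {
    cfg <- sim_config(
      n_samples = 700, n_variants = 10, n_taxa = 10, n_traits = 1,
      seed = 400 + i, maf_range = c(0.3, 0.5),
      effect_table = tibble::tibble(variant = 1L, taxon = 1L, beta = 1.2,
                                    channel = "AB"),
      causal_table = tibble::tibble(taxon = 1L, trait = 1L, alpha = 0,
                                    load_taxon = 1, load_trait = 1)
    )
    co <- simulate_cohort(cfg)
    x <- co$abundance$values[, 1]
    logx <- log10(pmax(x, half_min_pseudocount(x)))
    y <- co$traits$trait_1
    naive <- covariate_adjusted_assoc(setNames(logx, co$traits$sample_id), y)
    if (naive$p < 0.01) naive_sig <- naive_sig + 1
    score <- co$genotypes$dosage[, 1]
    est <- tsls(logx, y, score)
    ci <- est$beta + c(-1.96, 1.96) * est$se
    if (ci[1] <= 0 && ci[2] >= 0) covered <- covered + 1
  }
  expect_gte(naive_sig / n_rep, 0.9)   # confounding visible observationally
  expect_gte(covered / n_rep, 0.9)     # instrument immune to it
})

test_that("without confounding, TSLS and naive OLS agree", {
  cfg <- sim_config(
    n_samples = 1000, n_variants = 10, n_taxa = 10, n_traits = 1,
    seed = 777, maf_range = c(0.3, 0.5),
    effect_table = tibble::tibble(variant = 1L, taxon = 1L, beta = 1.2,
                                  channel = "AB"),
    causal_table = tibble::tibble(taxon = 1L, trait = 1L, alpha = 0.4,
                                  load_taxon = 0, load_trait = 0)
  )
  co <- simulate_cohort(cfg)
  x <- co$abundance$values[, 1]
  logx <- log10(pmax(x, half_min_pseudocount(x)))
  y <- co$traits$trait_1
  naive <- covariate_adjusted_assoc(setNames(logx, co$traits$sample_id), y)
  est <- tsls(logx, y, co$genotypes$dosage[, 1])
  expect_lt(abs(est$beta - naive$beta), 2 * est$se)
})

test_that("cohort round-trips through the on-disk formats", {
  co <- small_cohort("tiny", n_samples = 30, n_variants = 15, n_taxa = 8,
                     n_traits = 2, seed = 9)
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  expect_setequal(
    list.files(dir),
    c("genotypes.vcf", "abundance.tsv", "covariates.tsv", "traits.tsv",
      "truth.tsv")
  )
  g2 <- read_genotypes(file.path(dir, "genotypes.vcf"))
  expect_equal(unname(g2$dosage[rownames(co$genotypes$dosage),
                                co$genotypes$variants$variant_id]),
               unname(co$genotypes$dosage))
  a2 <- read_abundance(file.path(dir, "abundance.tsv"))
  expect_equal(unname(a2$values), unname(co$abundance$values),
               tolerance = 1e-6)
})
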