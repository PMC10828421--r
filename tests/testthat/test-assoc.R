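test_that("model dispatch follows the prevalence rule", {
  expect_equal(choose_model(0.96), "AB")
  expect_equal(choose_model(0.50), "PA")
  expect_equal(choose_model(0.951), "AB")
  expect_equal(choose_model(0.95), "PA")
  expect_error(choose_model(0.08), "filtered")
})

test_that("residualization matches the normal-equations oracle and handles zeros", {
  set.seed(1)
  n <- 10
  vals <- rexp(n) / 50
  vals[3] <- 0
  names(vals) <- sprintf("S%02d", 1:n)
  C <- matrix(rnorm(n * 2), n, 2,
              dimnames = list(names(vals), c("c1", "c2")))
  r <- residualize_log_abundance(vals, C)
  y <- log10(pmax(vals, min(vals[vals > 0]) / 2))
  X <- cbind(1, C)
  r_oracle <- y - X %*% solve(t(X) %*% X) %*% t(X) %*% y
  expect_equal(unname(r), unname(drop(r_oracle)), tolerance = 1e-10)
  expect_lt(abs(mean(r)), 1e-12)

  # y exactly linear in covariates -> residuals ~ 0
  y_lin <- 10^(1 + 2 * C[, 1])
  r2 <- residualize_log_abundance(setNames(y_lin, names(vals)), C,
                                  pseudocount = 1e-12)
  expect_lt(sqrt(sum(r2^2)), 1e-10)
})

test_that("linear and logistic fits match independent oracles on small fixtures", {
  set.seed(2)
  n <- 20
  dos <- rbinom(n, 2, 0.4)
  y <- 0.5 * dos + rnorm(n)
  fit <- linear_assoc(y, dos)
  o <- oracle_ols(cbind(1, dos), y, 2)
  expect_equal(fit$beta, o$beta, tolerance = 1e-8, ignore_attr = TRUE)
  expect_equal(fit$se, o$se, tolerance = 1e-8, ignore_attr = TRUE)
  expect_equal(fit$p, o$p, tolerance = 1e-8, ignore_attr = TRUE)

  pres <- rbinom(n, 1, plogis(-0.3 + 0.8 * dos))
  C <- matrix(rnorm(n), n, 1, dimnames = list(sprintf("S%02d", 1:n), "c1"))
  names(pres) <- rownames(C)
  dosn <- setNames(dos, rownames(C))
  lfit <- logistic_assoc(pres, dosn, C)
  lo <- oracle_logistic(cbind(1, dos, C), pres)
  expect_equal(lfit$beta, lo$beta[2], tolerance = 1e-8, ignore_attr = TRUE)
  expect_equal(lfit$se, lo$se[2], tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("monomorphic dosage is skipped; separable logistic fixture is flagged", {
  y <- rnorm(12)
  fit <- linear_assoc(y, rep(2, 12))
  expect_true(fit$skipped)
  # perfectly separated presence/absence
  dos <- c(rep(0, 6), rep(2, 6))
  pres <- c(rep(0, 6), rep(1, 6))
  lfit <- logistic_assoc(pres, dos)
  expect_true(lfit$skipped)
  expect_true(lfit$flag %in% c("separation", "non_converged"))
})

test_that("two-sided p is invariant under allele flip; beta changes sign", {
  set.seed(3)
  n <- 100
  dos <- rbinom(n, 2, 0.3)
  y <- 0.3 * dos + rnorm(n)
  f1 <- linear_assoc(y, dos)
  f2 <- linear_assoc(y, 2 - dos)
  expect_equal(f1$p, f2$p, tolerance = 1e-12)
  expect_equal(f1$beta, -f2$beta, tolerance = 1e-12)
})

test_that("planted effect is recovered within 3 SE at n = 1000", {
  set.seed(4)
  n <- 1000
  dos <- rbinom(n, 2, 0.3)
  y <- 0.5 * dos + rnorm(n)
  fit <- linear_assoc(y, dos)
  expect_lt(abs(fit$beta - 0.5), 3 * fit$se)
  expect_lt(fit$p, 5e-8)
})

test_that("diversity GWAS equals full multiple regression (oracle) and is calibrated", {
  co <- small_cohort("mid", n_samples = 300, n_variants = 100, n_taxa = 40,
                     seed = 11)
  g <- impute_dosage_mean(co$genotypes)
  y <- setNames(rnorm(300), rownames(g$dosage))
  res <- diversity_gwas(y, g, co$covariates)
  # oracle on 5 variants: coefficient from the full design
  C <- as.matrix(co$covariates[match(rownames(g$dosage),
                                     co$covariates$sample_id),
                               c("age", "sex", "bmi", "read_count")])
  for (j in c(1, 7, 33, 60, 99)) {
    o <- oracle_ols(cbind(1, g$dosage[, j], C), unname(y), 2)
    expect_equal(res$beta[j], o$beta, tolerance = 1e-10, ignore_attr = TRUE)
    expect_equal(res$se[j], o$se, tolerance = 1e-10, ignore_attr = TRUE)
    expect_equal(res$p[j], o$p, tolerance = 1e-10, ignore_attr = TRUE)
  }
})

test_that("a planted PCo effect reaches genome-wide significance with power", {
  # effect 0.4 SD per allele on a quantitative axis at n = 1500
  detected <- 0
  for (i in 1:20) {
    set.seed(500 + i)
    n <- 1500
    dos <- rbinom(n, 2, 0.3)
    y <- 0.4 / sd(dos) * dos + rnorm(n) # 0.4 SD of y per dosage SD
    fit <- linear_assoc(y, dos)
    if (!is.na(fit$p) && fit$p < 5e-8) detected <- detected + 1
  }
  expect_gte(detected, 16)
})

test_that("permuted phenotype gives calibrated inflation", {
  co <- small_cohort("calib", n_samples = 400, n_variants = 1200,
                     n_taxa = 10, seed = 31)
  g <- impute_dosage_mean(co$genotypes)
  set.seed(6)
  y <- setNames(sample(rnorm(400)), rownames(g$dosage))
  res <- diversity_gwas(y, g, co$covariates)
  lam <- lambda_gc(res$p[!res$skipped])
  expect_gt(lam, 0.9)
  expect_lt(lam, 1.1)
})

test_that("MANOVA scan matches stats::manova Pillai output and reduces to the linear model at k = 1", {
  co <- small_cohort("mid", n_samples = 300, n_variants = 100, n_taxa = 40,
                     seed = 11)
  g <- impute_dosage_mean(co$genotypes)
  ord <- pcoa(bray_curtis(co$abundance), k = 4)
  res <- manova_beta_gwas(ord, g, co$covariates)
  C <- as.matrix(co$covariates[match(rownames(g$dosage),
                                     co$covariates$sample_id),
                               c("age", "sex", "bmi", "read_count")])
  for (j in c(2, 17, 50)) {
    o <- oracle_pillai(ord$coordinates, g$dosage[, j], as.data.frame(C))
    expect_equal(res$pillai[j], unname(o["Pillai"]), tolerance = 1e-8)
    expect_equal(res$f_stat[j], unname(o["approx F"]), tolerance = 1e-8)
    expect_equal(res$p[j], unname(o["Pr(>F)"]), tolerance = 1e-8)
  }
  # univariate reduction: k = 1 equals the covariate-adjusted linear test
  res1 <- manova_beta_gwas(ord$coordinates[, 1, drop = FALSE], g,
                           co$covariates)
  lin <- diversity_gwas(setNames(ord$coordinates[, 1],
                                 rownames(ord$coordinates)),
                        g, co$covariates)
  expect_equal(res1$p, lin$p, tolerance = 1e-10)
})

test_that("MANOVA scan is calibrated under the null and powered for a planted shift", {
  set.seed(7)
  n <- 400
  k <- 5
  Y <- matrix(rnorm(n * k), n, k,
              dimnames = list(sprintf("S%04d", 1:n), NULL))
  G <- matrix(rbinom(n * 600, 2, 0.3), n, 600,
              dimnames = list(rownames(Y), sprintf("v%03d", 1:600)))
  res <- manova_beta_gwas(Y, G, NULL)
  p <- res$p[!res$skipped]
  expect_gt(suppressWarnings(ks.test(p, "punif"))$p.value, 0.01)

  # plant a dosage shift along axis 2
  Y2 <- Y
  Y2[, 2] <- Y2[, 2] + 0.35 * G[, 1]
  res2 <- manova_beta_gwas(Y2, G[, 1, drop = FALSE], NULL)
  expect_lt(res2$p, 1e-6)
})

test_that("lambda_gc hits its landmarks", {
  expect_equal(lambda_gc(rep(0.5, 200)), 1.0, tolerance = 1e-12)
  set.seed(8)
  chi <- rchisq(1e5, 1)
  p_unif <- pchisq(chi, 1, lower.tail = FALSE)
  expect_gt(lambda_gc(p_unif), 0.95)
  expect_lt(lambda_gc(p_unif), 1.05)
  p_infl <- pchisq(chi * 1.2, 1, lower.tail = FALSE)
  expect_equal(lambda_gc(p_infl), 1.2, tolerance = 0.02)
  expect_error(lambda_gc(c(rep(0.5, 99), 0)), "in \\(0, 1\\]")
  expect_error(lambda_gc(rep(0.5, 50)), "at least 100")
})

test_that("clumping follows the greedy p-ascending rule", {
  # A(p=1e-10, 1.0 Mb), B(p=1e-9, 1.4 Mb, r2_AB ~ 0.5),
  # C(p=1e-8, 1.6 Mb, r2_AC ~ 0) -> clumps {A, B} and {C}
  set.seed(9)
  n <- 500
  a <- rbinom(n, 2, 0.4)
  b <- ifelse(runif(n) < 0.75, a, rbinom(n, 2, 0.4)) # correlated with a
  c_ <- rbinom(n, 2, 0.4)
  stopifnot(cor(a, b)^2 > 0.2, cor(a, c_)^2 < 0.2)
  d <- cbind(A = a, B = b, C = c_)
  rownames(d) <- sprintf("S%04d", 1:n)
  g <- geno_matrix(d, tibble::tibble(
    variant_id = c("A", "B", "C"), chrom = "1",
    pos = c(1000000L, 1400000L, 1600000L), ref = "A", alt = "G"
  ))
  res <- tibble::tibble(variant_id = c("A", "B", "C"),
                        p = c(1e-10, 1e-9, 1e-8))
  cl <- clump_loci(res, g)
  expect_equal(cl$index_id, c("A", "C"))
  expect_setequal(cl$members[[1]], c("A", "B"))
  expect_equal(cl$members[[2]], "C")

  # distance rule: identical variants 2 Mb apart stay separate clumps
  g2 <- geno_matrix(cbind(X = a, Y = a) + 0,
                    tibble::tibble(variant_id = c("X", "Y"), chrom = "1",
                                   pos = c(1L, 2000001L), ref = "A",
                                   alt = "G"))
  rownames(g2$dosage) <- sprintf("S%04d", 1:n)
  cl2 <- clump_loci(tibble::tibble(variant_id = c("X", "Y"),
                                   p = c(1e-10, 1e-9)), g2)
  expect_equal(nrow(cl2), 2)

  # single significant variant -> one clump of one
  cl3 <- clump_loci(tibble::tibble(variant_id = "A", p = 1e-9), g)
  expect_equal(cl3$n_members, 1)

  # index variants are mutually independent under the stated rule
  for (i in seq_len(nrow(cl))) {
    for (j in seq_len(nrow(cl))) {
      if (i >= j) next
      dist_ij <- abs(cl$pos[i] - cl$pos[j])
      r2_ij <- cor(g$dosage[, cl$index_id[i]], g$dosage[, cl$index_id[j]])^2
      expect_true(dist_ij >= 1e6 || r2_ij < 0.2)
    }
  }
})

test_that("Bonferroni thresholds reproduce the study-wide and MR batch values", {
  expect_equal(signif(bonferroni_threshold(5e-8, 293), 3), 1.71e-10)
  expect_equal(signif(bonferroni_threshold(0.05, 402), 3), 1.24e-4)
  expect_equal(bonferroni_threshold(0.05, 1), 0.05)
  expect_error(bonferroni_threshold(0.05, 0), "positive integer")
})

test_that("planted AB and PA effects carry the correct sign almost always", {
  signs_ab <- signs_pa <- logical(0)
  for (i in 1:10) {
    set.seed(600 + i)
    n <- 1000
    dos <- rbinom(n, 2, 0.3)
    y <- 0.3 * dos + rnorm(n)           # standardized effect ~ 0.3
    signs_ab <- c(signs_ab, linear_assoc(y, dos)$beta > 0)
    pres <- rbinom(n, 1, plogis(-0.5 + 0.5 * dos))
    signs_pa <- c(signs_pa, logistic_assoc(pres, dos)$beta > 0)
  }
  expect_gte(mean(signs_ab), 0.95)
  expect_gte(mean(signs_pa), 0.95)
})
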