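# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: direct factorial enumeration, normal equations,
# and the closed-form single-instrument IV ratio.

# HWE exact test by brute-force enumeration of every heterozygote count,
# each configuration's probability computed from plain factorials
oracle_hwe <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  nA <- 2 * n_AA + n_Aa
  config_prob <- function(het) {
    aa_major <- (nA - het) / 2
    aa_minor <- n - aa_major - het
    exp(
      lfactorial(n) - lfactorial(aa_major) - lfactorial(het) -
        lfactorial(aa_minor) + het * log(2) +
        lfactorial(nA) + lfactorial(2 * n - nA) - lfactorial(2 * n)
    )
  }
  hets <- seq(min(nA, 2 * n - nA) %% 2, min(nA, 2 * n - nA), by = 2)
  probs <- vapply(hets, config_prob, numeric(1))
  p_obs <- probs[match(n_Aa, hets)]
  sum(probs[probs <= p_obs * (1 + 1e-9)])
}

# two-sided Fisher exact p by enumeration over all tables with the
# observed margins, using dhyper for each table's probability
oracle_fisher <- function(tab) {
  m <- sum(tab[1, ])
  n <- sum(tab[2, ])
  k <- sum(tab[, 1])
  support <- max(0, k - n):min(k, m)
  probs <- dhyper(support, m, n, k)
  p_obs <- dhyper(tab[1, 1], m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# OLS coefficient/SE/p for the coefficient of column `j` via raw normal
# equations (X includes its own intercept column)
oracle_ols <- function(X, y, j) {
  # center/scale the non-intercept columns for numerical stability; the
  # tested coefficient is rescaled back afterwards
  sds <- apply(X, 2, sd)
  keep_scale <- sds > 0
  Xs <- X
  Xs[, keep_scale] <- scale(X[, keep_scale, drop = FALSE])
  fit <- oracle_ols_raw(Xs, y, j)
  list(beta = fit$beta / sds[j], se = fit$se / sds[j], p = fit$p)
}

oracle_ols_raw <- function(X, y, j) {
  XtXinv <- solve(t(X) %*% X)
  b <- XtXinv %*% t(X) %*% y
  res <- y - X %*% b
  df <- nrow(X) - ncol(X)
  sigma2 <- sum(res^2) / df
  se <- sqrt(sigma2 * XtXinv[j, j])
  stat <- b[j] / se
  list(beta = b[j], se = se, p = 2 * pt(-abs(stat), df))
}

# single-instrument, no-covariate IV ratio estimator with its asymptotic SE
oracle_iv_ratio <- function(z, x, y) {
  beta <- cov(z, y) / cov(z, x)
  res <- (y - mean(y)) - beta * (x - mean(x))
  n <- length(y)
  zc <- z - mean(z)
  xc <- x - mean(x)
  # IV sandwich: Var(beta) = sum(z_c^2 res^2-ish); homoskedastic form used
  se <- sqrt(sum(res^2) / (n - 2) * sum(zc^2) / sum(zc * xc)^2)
  list(beta = beta, se = se)
}

# Newton-solver logistic regression, independent of glm.fit
oracle_logistic <- function(X, y, tol = 1e-12, maxit = 50) {
  b <- rep(0, ncol(X))
  for (i in seq_len(maxit)) {
    eta <- drop(X %*% b)
    mu <- 1 / (1 + exp(-eta))
    W <- mu * (1 - mu)
    score <- t(X) %*% (y - mu)
    info <- t(X) %*% (X * W)
    step <- solve(info, score)
    b <- b + drop(step)
    if (max(abs(step)) < tol) break
  }
  eta <- drop(X %*% b)
  mu <- 1 / (1 + exp(-eta))
  vcov <- solve(t(X) %*% (X * (mu * (1 - mu))))
  list(beta = b, se = sqrt(diag(vcov)))
}

# Pillai trace of the dosage term via stats::manova (dosage entered last)
oracle_pillai <- function(Y, x, C = NULL) {
  dat <- if (is.null(C)) data.frame(x = x) else data.frame(C, x = x)
  fit <- stats::manova(Y ~ ., data = dat)
  tab <- summary(fit, test = "Pillai")$stats
  tab["x", , drop = TRUE]
}

# small shared synthetic cohorts, memoized per test run
cohort_cache <- new.env(parent = emptyenv())
small_cohort <- function(key = "default", ...) {
  if (is.null(cohort_cache[[key]])) {
    cohort_cache[[key]] <- simulate_cohort(sim_config(...))
  }
  cohort_cache[[key]]
}
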