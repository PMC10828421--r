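#' Model dispatch by feature prevalence
#'
#' Core features present in more than 95% of samples are tested on
#' log10 relative abundance with a linear model (AB channel); features
#' present in 10-95% of samples are dichotomized to presence/absence and
#' tested with a logistic model (PA channel), avoiding zero inflation.
#' Features at or below 10% prevalence should have been removed by
#' [feature_qc()].
#'
#' @param prevalence fraction of samples with a nonzero value, in (0.10, 1].
#' @return `"AB"` or `"PA"`.
#' @export
choose_model <- function(prevalence) {
  stopifnot_scalar_prob(prevalence, "prevalence")
  if (prevalence <= 0.10) {
    abort("prevalence <= 0.10: feature should have been filtered out")
  }
  if (prevalence > 0.95) "AB" else "PA"
}

#' Residualize log10 abundance on covariates
#'
#' The AB channel's two-stage scheme: log10 relative abundance (zeros floored
#' at the per-feature half-minimum pseudocount) is regressed on the
#' covariates once, and the zero-mean residuals are then tested per variant
#' with a univariate regression.
#'
#' @param values relative abundances for one feature.
#' @param covariates covariate tibble or matrix.
#' @param pseudocount zero-replacement value; default the half-minimum rule.
#' @return numeric residual vector (mean zero), named by sample.
#' @export
residualize_log_abundance <- function(values, covariates,
                                      pseudocount = NULL) {
  if (any(values == 0) && is.null(pseudocount)) {
    pseudocount <- half_min_pseudocount(values)
  }
  y <- log10(pmax(values, pseudocount %||% 0))
  if (any(!is.finite(y))) abort("zero abundance with no pseudocount configured")
  C <- covariate_matrix(covariates, names(values))
  r <- drop(residualize_on(y, C))
  names(r) <- names(values)
  r
}

# vectorized per-variant OLS of y on each column of G (both already
# residualized on the same covariate set); df supplied explicitly so that
# the two-stage AB scheme (df = n - 2) and the in-model covariate scheme
# (df = n - n_cov - 2) share one code path
fast_linear_scan <- function(y, G, df) {
  n <- length(y)
  yc <- y - mean(y)
  Gc <- sweep(G, 2, colMeans(G))
  sxx <- colSums(Gc^2)
  sxy <- drop(crossprod(Gc, yc))
  syy <- sum(yc^2)
  ok <- sxx > 1e-12
  beta <- se <- p <- rep(NA_real_, ncol(G))
  beta[ok] <- sxy[ok] / sxx[ok]
  rss <- pmax(syy - sxy[ok]^2 / sxx[ok], 0)
  se[ok] <- sqrt(rss / df / sxx[ok])
  stat <- beta[ok] / se[ok]
  p[ok] <- 2 * pt(-abs(stat), df)
  tibble::tibble(
    variant_id = colnames(G) %||% sprintf("var%05d", seq_len(ncol(G))),
    n = n, beta = beta, se = se, p = p,
    skipped = !ok
  )
}

#' Linear association of residualized abundance with dosage
#'
#' Univariate slope t-test of precomputed residuals on ALT-allele dosage
#' (the AB channel's second stage). Monomorphic variants are skipped with a
#' reason code rather than an error.
#'
#' @param residuals output of [residualize_log_abundance()] (or any numeric
#'   response).
#' @param dosage numeric vector or samples x variants matrix.
#' @return tibble: `variant_id`, `n`, `beta`, `se`, `p`, `skipped`.
#' @export
linear_assoc <- function(residuals, dosage) {
  G <- if (is.matrix(dosage)) dosage else
    matrix(dosage, ncol = 1,
           dimnames = list(names(dosage), "dosage"))
  fast_linear_scan(residuals, G, df = length(residuals) - 2)
}

#' Logistic association of presence/absence with dosage
#'
#' Newton/IRLS logistic fit of the presence indicator on
#' `[1, dosage, covariates]` with a Wald z-test on the dosage coefficient.
#' Non-convergence or (quasi-)separation is reported as a flagged missing
#' result, never an exception.
#'
#' @param presence 0/1 vector.
#' @param dosage numeric vector or samples x variants matrix.
#' @param covariates covariate tibble or matrix (included in the model).
#' @return tibble: `variant_id`, `n`, `beta` (log-odds per ALT allele),
#'   `se`, `p`, `skipped`, `flag`.
#' @export
logistic_assoc <- function(presence, dosage, covariates = NULL) {
  G <- if (is.matrix(dosage)) dosage else
    matrix(dosage, ncol = 1, dimnames = list(names(dosage), "dosage"))
  C <- if (is.null(covariates)) NULL else
    covariate_matrix(covariates, rownames(G) %||% names(presence))
  n <- length(presence)
  m <- ncol(G)
  beta <- se <- p <- rep(NA_real_, m)
  flag <- character(m)
  for (j in seq_len(m)) {
    x <- G[, j]
    if (var(x) < 1e-12) {
      flag[j] <- "monomorphic"
      next
    }
    X <- cbind(1, x, C)
    fit <- tryCatch(
      suppressWarnings(glm.fit(X, presence, family = binomial())),
      error = function(e) NULL
    )
    if (is.null(fit) || !fit$converged || fit$boundary) {
      flag[j] <- "non_converged"
      next
    }
    pr <- fit$rank
    covmat <- tryCatch(
      chol2inv(fit$qr$qr[seq_len(pr), seq_len(pr), drop = FALSE]),
      error = function(e) NULL
    )
    se_j <- if (is.null(covmat)) NA_real_ else sqrt(covmat[2, 2])
    b_j <- fit$coefficients[2]
    if (!is.finite(se_j) || se_j > 100 || abs(b_j) > 15) {
      flag[j] <- "separation"
      next
    }
    beta[j] <- b_j
    se[j] <- se_j
    z <- b_j / se_j
    p[j] <- 2 * pnorm(-abs(z))
  }
  tibble::tibble(
    variant_id = colnames(G) %||% sprintf("var%05d", seq_len(m)),
    n = n, beta = beta, se = se, p = p,
    skipped = flag != "", flag = flag
  )
}

#' GWAS of a quantitative phenotype with in-model covariates
#'
#' Per-variant OLS of the phenotype on `[1, dosage, covariates]` — used for
#' alpha-diversity indices and community ordination axes. Implemented via
#' Frisch-Waugh residualization (phenotype and every dosage column are
#' residualized on the covariates, then a univariate regression with the
#' full-model residual df), which reproduces the full multiple regression
#' exactly.
#'
#' @param y named numeric phenotype vector.
#' @param g a [geno_matrix()] (QC'd, no missing dosages).
#' @param covariates covariate tibble or matrix.
#' @return tibble: variant metadata plus `n`, `beta`, `se`, `p`, `skipped`.
#' @export
diversity_gwas <- function(y, g, covariates = NULL) {
  ids <- rownames(g$dosage)
  if (!is.null(names(y))) y <- y[ids]
  C <- if (is.null(covariates)) NULL else covariate_matrix(covariates, ids)
  n <- length(y)
  df <- n - (if (is.null(C)) 0 else ncol(C)) - 2
  yr <- drop(residualize_on(y, C))
  Gr <- residualize_on(g$dosage, C)
  res <- fast_linear_scan(yr, Gr, df = df)
  res$variant_id <- g$variants$variant_id
  dplyr::left_join(res, g$variants[c("variant_id", "chrom", "pos")],
                   by = "variant_id") |>
    dplyr::relocate("chrom", "pos", .after = "variant_id")
}

#' Per-feature M-GWAS with prevalence dispatch
#'
#' Runs the AB channel (residualized log10 abundance, univariate linear
#' second stage) for features above 95% prevalence and the PA channel
#' (logistic with in-model covariates) for the rest, over all variants in
#' `g`. Covariates typically include age, sex, BMI, sequencing read count
#' and the top host genetic PCs.
#'
#' @param abundance an [abund_table()] (after [feature_qc()]).
#' @param g a [geno_matrix()] (after [variant_qc()] and imputation).
#' @param covariates covariate tibble.
#' @param features optional character vector restricting the feature set
#'   (e.g. the kept set from [greedy_representatives()]).
#' @return tibble with one row per feature x variant: `feature_id`, `model`,
#'   variant metadata, `n`, `beta`, `se`, `p`, `skipped`.
#' @export
feature_gwas <- function(abundance, g, covariates, features = NULL) {
  ids <- common_samples(rownames(abundance$values), rownames(g$dosage),
                        "abundance/genotypes")
  vals <- abundance$values[ids, , drop = FALSE]
  dos <- g$dosage[ids, , drop = FALSE]
  feats <- features %||% colnames(vals)
  out <- purrr::map(feats, function(f) {
    x <- vals[, f]
    prev <- mean(x > 0)
    model <- choose_model(prev)
    res <- if (model == "AB") {
      r <- residualize_log_abundance(setNames(x, ids), covariates)
      linear_assoc(r, dos)
    } else {
      logistic_assoc(as.numeric(x > 0), dos, covariates)
    }
    res$feature_id <- f
    res$model <- model
    res
  })
  res <- dplyr::bind_rows(out)
  dplyr::left_join(res, g$variants[c("variant_id", "chrom", "pos")],
                   by = "variant_id") |>
    dplyr::relocate("feature_id", "model", "variant_id", "chrom", "pos")
}

#' Genomic inflation factor
#'
#' `lambda_GC = median(qchisq(1 - p, 1)) / 0.4549364`: the ratio of the
#' observed median association chi-square to its null expectation. Values
#' near 1 indicate a calibrated test.
#'
#' @param p_values vector of p-values in (0, 1] (at least 100 for a stable
#'   estimate).
#' @return scalar inflation factor.
#' @export
lambda_gc <- function(p_values) {
  p_values <- p_values[!is.na(p_values)]
  if (length(p_values) < 100) abort("at least 100 p-values required")
  if (any(p_values <= 0 | p_values > 1)) abort("p-values must be in (0, 1]")
  median(qchisq(p_values, df = 1, lower.tail = FALSE)) / qchisq(0.5, 1)
}

#' Per-feature genomic inflation
#'
#' Features with fewer than 100 usable tests get `NA` (the median-based
#' estimator is too unstable there).
#'
#' @param results a [feature_gwas()] tibble.
#' @return tibble: `feature_id`, `model`, `n_tests`, `lambda_gc`.
#' @export
gwas_inflation <- function(results) {
  results |>
    dplyr::filter(!.data$skipped) |>
    dplyr::group_by(.data$feature_id, .data$model) |>
    dplyr::summarise(
      n_tests = dplyr::n(),
      lambda_gc = if (dplyr::n() >= 100) lambda_gc(.data$p) else NA_real_,
      .groups = "drop"
    )
}

#' Multivariate MANOVA scan of beta-diversity against dosage
#'
#' For each variant, the top community ordination axes (PCos) are regressed
#' jointly on `[1, dosage, covariates]` and the dosage term is tested with
#' Pillai's trace `V = tr(H (H + E)^{-1})` (H = hypothesis SSCP of the
#' dosage term fitted after the covariates, E = residual SSCP) and its
#' standard F approximation with `s = min(k, 1)`, `m = (|k - 1| - 1)/2`,
#' `n' = (nu_e - k - 1)/2`, `df1 = s(2m + s + 1)`, `df2 = s(2n' + s + 1)`.
#'
#' @param pcos an `ordination` or an n x k coordinate matrix (top PCos).
#' @param g a [geno_matrix()] or dosage matrix.
#' @param covariates covariate tibble or matrix.
#' @return tibble: `variant_id`, `pillai`, `f_stat`, `df1`, `df2`, `p`,
#'   `skipped`.
#' @export
manova_beta_gwas <- function(pcos, g, covariates = NULL) {
  Y <- if (inherits(pcos, "ordination")) pcos$coordinates else as.matrix(pcos)
  G <- if (inherits(g, "geno_matrix")) g$dosage else as.matrix(g)
  ids <- rownames(Y) %||% rownames(G)
  if (!is.null(rownames(Y)) && !is.null(rownames(G))) {
    ids <- common_samples(rownames(Y), rownames(G), "pcos/genotypes")
    Y <- Y[ids, , drop = FALSE]
    G <- G[ids, , drop = FALSE]
  }
  C <- if (is.null(covariates)) NULL else covariate_matrix(covariates, ids)
  n <- nrow(Y)
  k <- ncol(Y)
  p_cov <- 1 + (if (is.null(C)) 0 else ncol(C))
  nu_e <- n - p_cov - 1
  if (nu_e <= k) abort("residual SSCP singular: too few samples for k axes")
  Yr <- residualize_on(Y, C)
  Gr <- residualize_on(G, C)
  Tmat <- crossprod(Yr) # H + E for the dosage term
  Minv <- solve(Tmat)
  sxx <- colSums(Gr^2)
  Q <- crossprod(Yr, Gr) # k x m
  ok <- sxx > 1e-12
  V <- rep(NA_real_, ncol(G))
  V[ok] <- colSums(Q[, ok, drop = FALSE] * (Minv %*% Q[, ok, drop = FALSE])) /
    sxx[ok]
  V <- pmin(pmax(V, 0), 1)
  s <- 1
  m <- (abs(k - 1) - 1) / 2
  nprime <- (nu_e - k - 1) / 2
  df1 <- s * (2 * m + s + 1)
  df2 <- s * (2 * nprime + s + 1)
  f_stat <- (df2 / df1) * V / (1 - V)
  p <- pf(f_stat, df1, df2, lower.tail = FALSE)
  tibble::tibble(
    variant_id = colnames(G) %||% sprintf("var%05d", seq_len(ncol(G))),
    pillai = unname(V), f_stat = unname(f_stat), df1 = df1, df2 = df2,
    p = unname(ifelse(ok, p, NA_real_)), skipped = unname(!ok)
  )
}

#' Greedy LD clumping of association results
#'
#' Results with `p <= p_max` are processed in ascending p order: the best
#' unassigned variant becomes a clump index, and every unassigned variant on
#' the same chromosome within `window_bp` of it with dosage `r^2 >= r2`
#' joins its clump (`clump_rule = "and"`, the default: membership requires
#' both closeness and LD; `"or"` admits either). Index variants of distinct
#' clumps are therefore mutually independent under the complementary rule.
#'
#' @param results tibble with `variant_id` and `p` (rows with duplicate
#'   variants are collapsed to their minimum p).
#' @param g a [geno_matrix()] supplying positions and dosages for LD
#'   (composite LD: squared Pearson correlation of dosages).
#' @param window_bp distance window (default 1 Mb).
#' @param r2 LD threshold (default 0.2).
#' @param p_max significance cutoff (default 5e-8).
#' @param n_max stop after this many clumps (default unlimited).
#' @param clump_rule `"and"` (default) or `"or"`.
#' @return tibble: `index_id`, `index_p`, `chrom`, `pos`, `n_members`,
#'   `span_bp`, `members` (list column).
#' @export
clump_loci <- function(results, g, window_bp = 1e6, r2 = 0.2, p_max = 5e-8,
                       n_max = Inf, clump_rule = c("and", "or")) {
  clump_rule <- match.arg(clump_rule)
  empty_clumps <- tibble::tibble(
    index_id = character(), index_p = numeric(), chrom = character(),
    pos = integer(), n_members = integer(), span_bp = integer(),
    members = list()
  )
  sig <- dplyr::filter(results, !is.na(.data$p), .data$p <= p_max)
  if (nrow(sig) == 0) return(empty_clumps)
  hits <- sig |>
    dplyr::group_by(.data$variant_id) |>
    dplyr::summarise(p = min(.data$p), .groups = "drop") |>
    dplyr::left_join(g$variants[c("variant_id", "chrom", "pos")],
                     by = "variant_id") |>
    dplyr::arrange(.data$p)
  out <- list()
  while (nrow(hits) > 0 && length(out) < n_max) {
    idx <- hits[1, ]
    cand <- hits$chrom == idx$chrom & abs(hits$pos - idx$pos) < window_bp
    ld <- rep(NA_real_, nrow(hits))
    near <- which(cand)
    if (length(near) > 0) {
      x <- g$dosage[, idx$variant_id]
      ld[near] <- suppressWarnings(
        cor(x, g$dosage[, hits$variant_id[near], drop = FALSE])
      )^2
    }
    in_clump <- if (clump_rule == "and") {
      cand & !is.na(ld) & ld >= r2
    } else {
      cand | (!is.na(ld) & ld >= r2)
    }
    in_clump[1] <- TRUE
    members <- hits$variant_id[in_clump]
    span <- if (length(members) > 1) {
      diff(range(hits$pos[in_clump]))
    } else 0L
    out[[length(out) + 1]] <- tibble::tibble(
      index_id = idx$variant_id, index_p = idx$p,
      chrom = idx$chrom, pos = idx$pos,
      n_members = length(members), span_bp = as.integer(span),
      members = list(members)
    )
    hits <- hits[!in_clump, , drop = FALSE]
  }
  if (length(out) == 0) return(empty_clumps)
  dplyr::bind_rows(out)
}

#' Bonferroni-corrected significance threshold
#'
#' `alpha / m` — e.g. the study-wide threshold 5e-8 / 293 = 1.71e-10 for 293
#' independent M-GWAS tests, or 0.05 / 402 = 1.24e-4 for a batch of 402
#' Mendelian-randomization pairs.
#'
#' @param alpha family-wise error rate.
#' @param m number of tests (>= 1).
#' @return the corrected per-test threshold.
#' @export
bonferroni_threshold <- function(alpha, m) {
  if (length(m) != 1 || m < 1 || m != round(m)) {
    abort("`m` must be a positive integer count")
  }
  alpha / m
}
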