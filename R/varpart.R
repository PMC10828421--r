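#' Distance-based redundancy analysis R-squared
#'
#' The dissimilarity matrix is embedded by [pcoa()] (positive-eigenvalue axes
#' scaled by the square roots of their eigenvalues), the axes are regressed
#' jointly on the predictors, and R-squared is the fitted sum of squares over
#' the total inertia (the sum of positive eigenvalues). The adjusted value
#' uses the Ezekiel correction `1 - (1 - R^2)(n - 1)/(n - p - 1)`. Negative
#' eigenvalues are excluded from the total inertia. Marginal contributions
#' (drop-one R-squared losses) are reported per predictor.
#'
#' @param d a `dist` or symmetric dissimilarity matrix.
#' @param X predictor matrix or data frame (n rows; no intercept column).
#' @return a `dbrda_result`: `r2`, `adj_r2`, `n`, `n_predictors`, `marginal`
#'   tibble.
#' @export
dbrda_r2 <- function(d, X) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- sprintf("x%d", seq_len(ncol(X)))
  zero_var <- apply(X, 2, var) < 1e-12
  if (any(zero_var)) {
    abort(sprintf("zero-variance predictor: %s",
                  paste(colnames(X)[zero_var], collapse = ", ")))
  }
  ord <- pcoa(d)
  n <- nrow(ord$coordinates)
  if (n <= ncol(X) + 1) abort("n must exceed the number of predictors + 1")
  total <- sum(ord$eigenvalues[ord$eigenvalues > 0])
  r2 <- dbrda_r2_axes(ord$coordinates, X, total)
  p <- ncol(X)
  marginal <- tibble::tibble(
    predictor = colnames(X),
    marginal_r2 = vapply(seq_len(p), function(j) {
      if (p == 1) return(r2)
      r2 - dbrda_r2_axes(ord$coordinates, X[, -j, drop = FALSE], total)
    }, numeric(1))
  )
  structure(list(
    r2 = r2, adj_r2 = ezekiel_adj(r2, n, p), n = n, n_predictors = p,
    marginal = marginal
  ), class = "dbrda_result")
}

# fitted-inertia fraction of already-embedded axes on X
dbrda_r2_axes <- function(axes, X, total = sum(axes^2), strict = TRUE) {
  fitted <- axes - residualize_on(axes, X, strict = strict)
  # axes are centered, so the intercept absorbs nothing
  sum(fitted^2) / total
}

ezekiel_adj <- function(r2, n, p) 1 - (1 - r2) * (n - 1) / (n - p - 1)

#' @export
print.dbrda_result <- function(x, ...) {
  cat(sprintf("<dbrda> R2 = %.4f, adjusted R2 = %.4f (n = %d, p = %d)\n",
              x$r2, x$adj_r2, x$n, x$n_predictors))
  invisible(x)
}

#' Tidy dbRDA marginal contributions
#' @param x a `dbrda_result`.
#' @param ... unused.
#' @return tibble of per-predictor marginal R-squared contributions.
#' @method tidy dbrda_result
#' @export
tidy.dbrda_result <- function(x, ...) x$marginal

#' dbRDA fit summary
#' @param x a `dbrda_result`.
#' @param ... unused.
#' @return one-row tibble: `r2`, `adj_r2`, `n`, `n_predictors`.
#' @method glance dbrda_result
#' @export
glance.dbrda_result <- function(x, ...) {
  tibble::tibble(r2 = x$r2, adj_r2 = x$adj_r2, n = x$n,
                 n_predictors = x$n_predictors)
}

#' Forward selection of beta-diversity predictors
#'
#' Starting from an empty model, each step adds the candidate that maximizes
#' the adjusted R-squared, provided (a) the adjusted R-squared strictly
#' increases, (b) the candidate's permutation p-value (gain in fit under row
#' permutation of the residualized response) is at most `alpha_in`, and (c)
#' the cumulative adjusted R-squared does not exceed that of the
#' all-candidates model — the usual guards against overselection. Stops when
#' no candidate qualifies.
#'
#' @param d a `dist`, a symmetric dissimilarity matrix, or a precomputed
#'   [pcoa()] `ordination` (all positive axes).
#' @param candidates matrix or data frame of candidate predictors (n rows,
#'   named columns).
#' @param alpha_in permutation p-value threshold for entry (default 0.05).
#' @param n_perm permutations per entry test (default 199).
#' @param seed integer seed for the permutations.
#' @param r2_scope apply guard (c), the adjusted-R-squared ceiling of the
#'   all-candidates model (default `TRUE`). With many pure-noise candidates
#'   this ceiling is itself estimated with error and can block a genuine
#'   first entry; set `FALSE` to rely on guards (a) and (b) alone.
#' @return tibble of selected predictors in entry order with `step`,
#'   `predictor`, `adj_r2_cum` (cumulative adjusted R-squared), `perm_p`;
#'   `attr(, "global_adj_r2")` is the all-candidates ceiling.
#' @export
forward_select <- function(d, candidates, alpha_in = 0.05, n_perm = 199,
                           seed = 1, r2_scope = TRUE) {
  X <- as.matrix(candidates)
  if (is.null(colnames(X))) colnames(X) <- sprintf("x%d", seq_len(ncol(X)))
  if (ncol(X) < 1) abort("at least one candidate required")
  ord <- if (inherits(d, "ordination")) d else pcoa(d)
  axes <- ord$coordinates
  n <- nrow(axes)
  total <- sum(ord$eigenvalues[ord$eigenvalues > 0])
  n_all <- min(ncol(X), n - 2)
  global_adj <- ezekiel_adj(
    dbrda_r2_axes(axes, X[, seq_len(n_all), drop = FALSE], total,
                  strict = FALSE),
    n, n_all
  )
  set.seed(seed)
  selected <- character()
  remaining <- colnames(X)
  adj_cur <- 0
  rows <- list()
  while (length(remaining) > 0 && length(selected) < n - 2) {
    p_new <- length(selected) + 1
    cand_adj <- vapply(remaining, function(v) {
      ezekiel_adj(
        dbrda_r2_axes(axes, X[, c(selected, v), drop = FALSE], total,
                      strict = FALSE),
        n, p_new
      )
    }, numeric(1))
    best <- names(which.max(cand_adj))
    best_adj <- cand_adj[best]
    if (best_adj <= adj_cur + 1e-12) break
    if (r2_scope && best_adj > global_adj + 1e-12) break
    # permutation entry test: permute the response residualized on the
    # current model, keep the candidate (residualized likewise) fixed
    R_axes <- if (length(selected) == 0) {
      scale(axes, scale = FALSE)
    } else {
      residualize_on(axes, X[, selected, drop = FALSE])
    }
    v_res <- drop(if (length(selected) == 0) {
      scale(X[, best], scale = FALSE)
    } else {
      residualize_on(X[, best], X[, selected, drop = FALSE])
    })
    gain_obs <- sum(crossprod(v_res, R_axes)^2) / sum(v_res^2)
    gains <- vapply(seq_len(n_perm), function(i) {
      pr <- sample.int(n)
      sum(crossprod(v_res, R_axes[pr, , drop = FALSE])^2) / sum(v_res^2)
    }, numeric(1))
    perm_p <- (1 + sum(gains >= gain_obs)) / (n_perm + 1)
    if (perm_p > alpha_in) break
    selected <- c(selected, best)
    remaining <- setdiff(remaining, best)
    adj_cur <- best_adj
    rows[[length(rows) + 1]] <- tibble::tibble(
      step = length(selected), predictor = best,
      adj_r2_cum = best_adj, perm_p = perm_p
    )
  }
  out <- if (length(rows) == 0) {
    tibble::tibble(step = integer(), predictor = character(),
                   adj_r2_cum = numeric(), perm_p = numeric())
  } else {
    dplyr::bind_rows(rows)
  }
  attr(out, "global_adj_r2") <- global_adj
  out
}

#' Permutation null for genotype-explained beta-diversity variance
#'
#' The observed pipeline: a Pillai-trace MANOVA scan of the top community
#' axes against every variant, greedy clumping of the scan into the top
#' `n_top` loci, then [forward_select()] of the lead variants' dosages with
#' the cumulative adjusted R-squared as the variance explained by genotype.
#' Each permutation randomly reassigns whole species profiles to individuals
#' (a row permutation of the abundance table; the genotype matrix is left
#' untouched, preserving host structure under the null) and re-runs the same
#' scan-clump-select pipeline, so selection bias is shared between observed
#' and permuted runs. The empirical p is the fraction of permutations whose
#' explained variance is at least the observed one; a one-sample t-test
#' p-value of the permuted values against the observed is also reported.
#'
#' @param a an [abund_table()].
#' @param g a [geno_matrix()] (imputed).
#' @param covariates covariate tibble.
#' @param n_top number of lead loci carried into the variance model
#'   (default 21).
#' @param n_perm number of permutations (default 100, >= 1).
#' @param seed integer seed.
#' @param k number of ordination axes scanned (default 10).
#' @param clump_r2,clump_window_bp clumping parameters.
#' @param fs_alpha_in,fs_n_perm forward-selection entry threshold and inner
#'   permutation count.
#' @param tail `"inclusive"` (default; the plain fraction with `>=`) or
#'   `"add_one"` for the (k + 1)/(n + 1) estimator.
#' @return a `perm_null`: `observed_r2`, `permuted_r2`, `empirical_p`,
#'   `t_test_p`, `n_selected`.
#' @export
snp_variance_permutation_null <- function(a, g, covariates = NULL,
                                          n_top = 21, n_perm = 100, seed = 1,
                                          k = 10, clump_r2 = 0.2,
                                          clump_window_bp = 1e6,
                                          fs_alpha_in = 0.05, fs_n_perm = 39,
                                          tail = c("inclusive", "add_one")) {
  tail <- match.arg(tail)
  if (n_perm < 1) abort("`n_perm` must be >= 1")
  ids <- common_samples(rownames(a$values), rownames(g$dosage),
                        "abundance/genotypes")
  g$dosage <- g$dosage[ids, , drop = FALSE]
  vals <- a$values[ids, , drop = FALSE]
  C <- if (is.null(covariates)) NULL else covariate_matrix(covariates, ids)
  dosage_checksum <- sum(g$dosage)

  ord_full <- pcoa(bray_curtis(vals)) # all positive axes: total inertia
  axes_full <- ord_full$coordinates
  axes_scan <- axes_full[, seq_len(min(k, ncol(axes_full))), drop = FALSE]

  one_run <- function(perm, run_seed) {
    scan_axes <- axes_scan[perm, , drop = FALSE]
    rownames(scan_axes) <- rownames(axes_scan)
    scan <- manova_beta_gwas(scan_axes, g, C)
    clumps <- clump_loci(scan, g, window_bp = clump_window_bp, r2 = clump_r2,
                         p_max = 1, n_max = n_top)
    leads <- clumps$index_id
    if (length(leads) == 0) return(list(r2 = 0, n_sel = 0L))
    ord_perm <- ord_full
    ord_perm$coordinates <- axes_full[perm, , drop = FALSE]
    rownames(ord_perm$coordinates) <- rownames(axes_full)
    sel <- forward_select(
      ord_perm, g$dosage[, leads, drop = FALSE],
      alpha_in = fs_alpha_in, n_perm = fs_n_perm, seed = run_seed
    )
    if (nrow(sel) == 0) {
      list(r2 = 0, n_sel = 0L)
    } else {
      list(r2 = max(sel$adj_r2_cum), n_sel = nrow(sel))
    }
  }

  n <- nrow(axes_full)
  obs <- one_run(seq_len(n), run_seed = seed)
  set.seed(seed)
  perm_seeds <- sample.int(.Machine$integer.max %/% 2, n_perm)
  permuted <- vapply(seq_len(n_perm), function(i) {
    set.seed(perm_seeds[i])
    one_run(sample.int(n), run_seed = perm_seeds[i])$r2
  }, numeric(1))
  stopifnot(sum(g$dosage) == dosage_checksum) # genotypes untouched
  emp <- if (tail == "inclusive") {
    mean(permuted >= obs$r2)
  } else {
    (1 + sum(permuted >= obs$r2)) / (n_perm + 1)
  }
  structure(list(
    observed_r2 = obs$r2, permuted_r2 = permuted, empirical_p = emp,
    t_test_p = tryCatch(
      t.test(permuted, mu = obs$r2, alternative = "less")$p.value,
      error = function(e) NA_real_
    ),
    n_selected = obs$n_sel, n_perm = n_perm
  ), class = "perm_null")
}

#' @export
print.perm_null <- function(x, ...) {
  cat(sprintf(
    "<perm_null> observed adj R2 = %.4f, mean permuted = %.4f, empirical p = %.3f\n",
    x$observed_r2, mean(x$permuted_r2), x$empirical_p
  ))
  invisible(x)
}

#' Tidy a permutation null
#' @param x a `perm_null`.
#' @param ... unused.
#' @return tibble of permutation replicates and their explained variance.
#' @method tidy perm_null
#' @export
tidy.perm_null <- function(x, ...) {
  tibble::tibble(permutation = seq_along(x$permuted_r2),
                 adj_r2 = x$permuted_r2)
}

#' Permutation-null summary
#' @param x a `perm_null`.
#' @param ... unused.
#' @return one-row tibble: observed variance, permutation mean, empirical
#'   and t-test p-values.
#' @method glance perm_null
#' @export
glance.perm_null <- function(x, ...) {
  tibble::tibble(
    observed_r2 = x$observed_r2, mean_permuted_r2 = mean(x$permuted_r2),
    empirical_p = x$empirical_p, t_test_p = x$t_test_p,
    n_selected = x$n_selected, n_perm = x$n_perm
  )
}
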