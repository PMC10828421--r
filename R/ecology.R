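#' Per-sample alpha diversity
#'
#' Shannon index in natural log units (`-sum p log p`, with `0 log 0 = 0`)
#' and the Gini-Simpson index (`1 - sum p^2`), computed on row-renormalized
#' proportions via \pkg{vegan}.
#'
#' @param a an [abund_table()].
#' @return tibble: `sample_id`, `shannon`, `simpson`.
#' @export
alpha_diversity <- function(a) {
  vals <- a$values
  rs <- rowSums(vals)
  if (any(rs == 0)) {
    abort(sprintf("all-zero abundance row for sample %s",
                  rownames(vals)[which(rs == 0)[1]]))
  }
  tibble::tibble(
    sample_id = rownames(vals),
    shannon = as.numeric(vegan::diversity(vals, index = "shannon")),
    simpson = as.numeric(vegan::diversity(vals, index = "simpson"))
  )
}

#' Bray-Curtis dissimilarity matrix
#'
#' `BC(x, y) = sum |x_i - y_i| / sum (x_i + y_i)`, in [0, 1], via
#' \pkg{vegan}'s `vegdist`.
#'
#' @param a an [abund_table()] or a non-negative samples x features matrix.
#' @return a `dist` object with sample labels.
#' @export
bray_curtis <- function(a) {
  vals <- if (inherits(a, "abund_table")) a$values else as.matrix(a)
  zero_rows <- rowSums(vals) == 0
  if (sum(zero_rows) >= 2) {
    abort("two or more all-zero samples: Bray-Curtis undefined for those pairs")
  }
  vegan::vegdist(vals, method = "bray")
}

#' Principal coordinates analysis
#'
#' Classical metric scaling: the squared dissimilarity matrix is
#' Gower-double-centered (`G = -1/2 J D^2 J`), eigendecomposed, and
#' coordinates are eigenvectors scaled by the square root of their (positive)
#' eigenvalues. Negative eigenvalues — possible for non-Euclidean
#' dissimilarities such as Bray-Curtis — are reported but their axes dropped;
#' no Lingoes/Cailliez correction is applied. Proportions explained are
#' relative to the sum of positive eigenvalues. Axis signs follow the
#' convention that the largest-magnitude loading is positive.
#'
#' @param d a `dist` or symmetric matrix of dissimilarities.
#' @param k number of axes to return (default all positive axes).
#' @return an `ordination` object: `coordinates` (n x k), `eigenvalues`
#'   (all, descending), `prop_explained`, `negative_eigenvalues`.
#' @export
pcoa <- function(d, k = NULL) {
  D <- as.matrix(d)
  if (max(abs(D - t(D))) > 1e-12) abort("dissimilarity matrix must be symmetric")
  n <- nrow(D)
  # Gower double-centering: center rows, then columns, of -D^2/2
  G <- t(scale(t(-0.5 * D^2), scale = FALSE, center = TRUE))
  G <- scale(G, scale = FALSE, center = TRUE)
  G <- (G + t(G)) / 2
  attr(G, "scaled:center") <- NULL
  e <- eigen(G, symmetric = TRUE)
  ev <- e$values
  tol <- 1e-9 * max(abs(ev), 1)
  pos <- which(ev > tol)
  k <- min(k %||% length(pos), length(pos), n - 1)
  coords <- e$vectors[, pos[seq_len(k)], drop = FALSE] %*%
    diag(sqrt(ev[pos[seq_len(k)]]), k)
  coords <- fix_axis_signs(coords)
  rownames(coords) <- rownames(D) %||% sprintf("S%04d", seq_len(n))
  colnames(coords) <- sprintf("PCo%d", seq_len(k))
  new_ordination(coords, ev, prop = ev[pos[seq_len(k)]] / sum(ev[pos]),
                 negative = ev[ev < -tol])
}

fix_axis_signs <- function(coords) {
  for (j in seq_len(ncol(coords))) {
    i <- which.max(abs(coords[, j]))
    if (coords[i, j] < 0) coords[, j] <- -coords[, j]
  }
  coords
}

new_ordination <- function(coords, eigenvalues, prop, negative = numeric()) {
  structure(list(
    coordinates = coords, eigenvalues = eigenvalues,
    prop_explained = prop, negative_eigenvalues = negative
  ), class = "ordination")
}

#' @export
print.ordination <- function(x, ...) {
  cat(sprintf("<ordination> %d samples, %d axes (%.1f%% on axis 1)\n",
              nrow(x$coordinates), ncol(x$coordinates),
              100 * x$prop_explained[1]))
  invisible(x)
}

#' Tidy an ordination
#' @param x an `ordination`.
#' @param ... unused.
#' @return tibble with `sample_id` and one column per axis.
#' @method tidy ordination
#' @export
tidy.ordination <- function(x, ...) {
  tibble::as_tibble(x$coordinates, rownames = "sample_id")
}

#' Ordination summary
#' @param x an `ordination`.
#' @param ... unused.
#' @return one-row tibble: axes retained, variance on the first axis,
#'   number of negative eigenvalues.
#' @method glance ordination
#' @export
glance.ordination <- function(x, ...) {
  tibble::tibble(
    n_axes = ncol(x$coordinates),
    prop_axis1 = x$prop_explained[1],
    n_negative_eigenvalues = length(x$negative_eigenvalues)
  )
}

#' Principal components of a genotype matrix
#'
#' Each variant is standardized as `(g - 2p) / sqrt(2 p (1 - p))` with `p`
#' the ALT-allele frequency, then the top-k left singular vectors (scaled by
#' their singular values) are the sample PCs — the usual GWAS population
#' structure axes. Monomorphic variants are excluded with a warning; missing
#' dosages must be imputed first.
#'
#' @param g a [geno_matrix()] without missing dosages.
#' @param k number of components (default 10).
#' @return an `ordination` with axes named `PC1..PCk`.
#' @export
genotype_pca <- function(g, k = 10) {
  d <- g$dosage
  if (anyNA(d)) abort("missing dosages: run impute_dosage_mean() first")
  p <- colMeans(d) / 2
  mono <- p <= 0 | p >= 1
  if (any(mono)) {
    warn(sprintf("excluding %d monomorphic variant(s) from PCA", sum(mono)))
    d <- d[, !mono, drop = FALSE]
    p <- p[!mono]
  }
  X <- sweep(sweep(d, 2, 2 * p), 2, sqrt(2 * p * (1 - p)), "/")
  k <- min(k, nrow(X) - 1, ncol(X))
  s <- svd(X, nu = k, nv = 0)
  coords <- fix_axis_signs(s$u %*% diag(s$d[seq_len(k)], k))
  rownames(coords) <- rownames(d)
  colnames(coords) <- sprintf("PC%d", seq_len(k))
  ev <- s$d^2 / (nrow(X) - 1)
  new_ordination(coords, ev, prop = ev[seq_len(k)] / sum(ev))
}

#' Covariate-adjusted linear association
#'
#' OLS of `y` on `[1, x, covariates]`; reports the coefficient of `x`, its
#' classical SE and the two-sided t-test p-value. This is the multivariable
#' linear model used to relate host genetic PCs to diversity indices and
#' community axes.
#'
#' @param x,y aligned numeric vectors.
#' @param covariates optional covariate tibble/matrix (aligned rows, or with
#'   a `sample_id` column matching `names(x)`).
#' @return one-row tibble: `beta`, `se`, `statistic`, `p`, `n`.
#' @export
covariate_adjusted_assoc <- function(x, y, covariates = NULL) {
  C <- if (is.null(covariates)) NULL else covariate_matrix(covariates, names(x))
  n <- length(y)
  X <- cbind(`(Intercept)` = 1, x = x, C)
  if (n <= ncol(X) + 1) abort("too few samples for the requested covariates")
  qr_X <- qr(X)
  if (qr_X$rank < ncol(X)) {
    abort(sprintf("rank-deficient design (collinear: %s)",
                  paste(colnames(X)[-seq_len(qr_X$rank)], collapse = ", ")))
  }
  fit <- lm.fit(X, y)
  df <- n - ncol(X)
  sigma2 <- sum(fit$residuals^2) / df
  XtXinv <- chol2inv(qr.R(qr_X))
  se <- sqrt(sigma2 * XtXinv[2, 2])
  beta <- fit$coefficients[["x"]]
  stat <- beta / se
  tibble::tibble(beta = beta, se = se, statistic = stat,
                 p = 2 * pt(-abs(stat), df), n = n)
}

#' Wilcoxon rank-sum test p-value
#'
#' Exact two-sided p by enumeration for small untied samples
#' (`n_x + n_y <= 20`), tie-corrected normal approximation otherwise; a
#' degenerate comparison with all values identical returns p = 1.
#'
#' @param x,y numeric vectors (both nonempty).
#' @return two-sided p-value.
#' @export
wilcoxon_rank_sum <- function(x, y) {
  if (length(x) == 0 || length(y) == 0) abort("both groups must be nonempty")
  if (length(unique(c(x, y))) == 1L) return(1)
  ties <- any(duplicated(c(x, y)))
  exact <- !ties && (length(x) + length(y)) <= 20
  suppressWarnings(
    wilcox.test(x, y, exact = exact, correct = !exact)$p.value
  )
}
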