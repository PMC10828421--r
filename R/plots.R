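#' QQ plot of association p-values
#'
#' Observed versus expected -log10 p under the uniform null, with the
#' genomic inflation factor in the subtitle.
#'
#' @param results tibble with a `p` column (e.g. from [feature_gwas()] or
#'   [diversity_gwas()]).
#' @return a ggplot object.
#' @export
plot_qq <- function(results) {
  p <- sort(results$p[!is.na(results$p)])
  df <- tibble::tibble(
    expected = -log10(stats::ppoints(length(p))),
    observed = -log10(p)
  )
  lambda <- if (length(p) >= 100) lambda_gc(p) else NA_real_
  ggplot2::ggplot(df, ggplot2::aes(x = .data$expected, y = .data$observed)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey50") +
    ggplot2::geom_point(size = 0.6) +
    ggplot2::labs(
      x = expression(Expected ~ -log[10](italic(p))),
      y = expression(Observed ~ -log[10](italic(p))),
      subtitle = if (is.na(lambda)) NULL else
        sprintf("lambda[GC] = %.3f", lambda)
    ) +
    ggplot2::theme_minimal()
}

#' Manhattan plot of association results
#'
#' @param results tibble with `chrom`, `pos` and `p` columns.
#' @param genome_wide,study_wide significance lines (default 5e-8 and none).
#' @return a ggplot object.
#' @export
plot_manhattan <- function(results, genome_wide = 5e-8, study_wide = NULL) {
  df <- dplyr::filter(results, !is.na(.data$p))
  gg <- ggplot2::ggplot(df, ggplot2::aes(
    x = .data$pos, y = -log10(.data$p), colour = .data$chrom
  )) +
    ggplot2::geom_point(size = 0.5, show.legend = FALSE) +
    ggplot2::geom_hline(yintercept = -log10(genome_wide), linetype = 2,
                        colour = "grey40") +
    ggplot2::labs(x = "Position (bp)",
                  y = expression(-log[10](italic(p)))) +
    ggplot2::theme_minimal()
  if (!is.null(study_wide)) {
    gg <- gg + ggplot2::geom_hline(yintercept = -log10(study_wide),
                                   linetype = 1, colour = "black")
  }
  gg
}

#' Ordination scatter plot
#'
#' @param object an `ordination` (from [pcoa()] or [genotype_pca()]).
#' @param axes pair of axis indices to plot (default first two).
#' @param colour_by optional named vector (e.g. subpopulation labels) used
#'   to colour samples.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot ordination
#' @export
autoplot.ordination <- function(object, axes = c(1, 2), colour_by = NULL,
                                ...) {
  co <- object$coordinates
  df <- tibble::tibble(
    sample_id = rownames(co),
    x = co[, axes[1]],
    y = co[, axes[2]]
  )
  lab <- function(i) sprintf("%s (%.1f%%)", colnames(co)[i],
                             100 * object$prop_explained[i])
  gg <- if (is.null(colour_by)) {
    ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y))
  } else {
    df$group <- colour_by[df$sample_id]
    ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                     colour = .data$group))
  }
  gg + ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = lab(axes[1]), y = lab(axes[2]), colour = NULL) +
    ggplot2::theme_minimal()
}

#' Permutation-null histogram
#'
#' Permuted explained-variance distribution with the observed value marked.
#'
#' @param object a `perm_null` from [snp_variance_permutation_null()].
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot perm_null
#' @export
autoplot.perm_null <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(x = .data$adj_r2)) +
    ggplot2::geom_histogram(bins = 20, fill = "grey70", colour = "grey30") +
    ggplot2::geom_vline(xintercept = object$observed_r2, colour = "red") +
    ggplot2::labs(
      x = "Adjusted R-squared (permuted)",
      subtitle = sprintf("observed = %.4f, empirical p = %.3f",
                         object$observed_r2, object$empirical_p)
    ) +
    ggplot2::theme_minimal()
}
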