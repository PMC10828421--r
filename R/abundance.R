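#' Relative-abundance container
#'
#' An `abund_table` holds a samples x features matrix of relative abundances
#' in [0, 1] plus per-feature metadata (clade label, prevalence = fraction of
#' samples with a nonzero value, mean relative abundance). Rows may sum to
#' less than 1 after feature filtering (sub-compositions are allowed), never
#' to more than 1 beyond numerical noise.
#'
#' @param values numeric matrix, samples in rows, features in columns;
#'   non-negative.
#' @param features optional tibble with `feature_id` (and optionally
#'   `clade_name`) per feature; prevalence and mean abundance are recomputed.
#' @return an object of class `abund_table`.
#' @export
abund_table <- function(values, features = NULL) {
  values <- as.matrix(values)
  if (any(values < 0, na.rm = TRUE)) abort("abundances must be non-negative")
  rs <- rowSums(values)
  if (any(rs > 1 + 1e-6)) abort("abundance rows must sum to <= 1")
  if (is.null(rownames(values))) {
    rownames(values) <- sprintf("S%04d", seq_len(nrow(values)))
  }
  if (is.null(colnames(values))) {
    colnames(values) <- sprintf("t%03d", seq_len(ncol(values)))
  }
  if (is.null(features)) {
    features <- tibble::tibble(
      feature_id = colnames(values),
      clade_name = colnames(values)
    )
  }
  features <- tibble::as_tibble(features)
  if (nrow(features) != ncol(values)) {
    abort("feature table and value matrix dimensions disagree")
  }
  features$prevalence <- colMeans(values > 0)
  features$mean_abundance <- colMeans(values)
  structure(list(values = values, features = features), class = "abund_table")
}

#' @export
print.abund_table <- function(x, ...) {
  cat(sprintf(
    "<abund_table> %d samples x %d features (prevalence %.2f-%.2f)\n",
    nrow(x$values), ncol(x$values),
    min(x$features$prevalence), max(x$features$prevalence)
  ))
  invisible(x)
}

#' @export
dim.abund_table <- function(x) dim(x$values)

#' Tidy an abundance table
#' @param x an [abund_table()].
#' @param ... unused.
#' @return a long tibble: `sample_id`, `feature_id`, `abundance`.
#' @method tidy abund_table
#' @export
tidy.abund_table <- function(x, ...) {
  tibble::as_tibble(x$values, rownames = "sample_id") |>
    tidyr::pivot_longer(-"sample_id",
      names_to = "feature_id", values_to = "abundance"
    )
}

#' Feature-level quality control
#'
#' Keeps features whose prevalence and mean relative abundance are strictly
#' above the thresholds ("over 10%" / "over 1e-4"), the usual M-GWAS
#' pre-filter that removes rare, low-signal features before testing.
#'
#' @param a an [abund_table()].
#' @param prevalence_min prevalence threshold, strict (default 0.10).
#' @param mean_abund_min mean relative abundance threshold, strict
#'   (default `1e-4`).
#' @return filtered `abund_table`; `attr(, "qc_report")` counts removals.
#' @export
feature_qc <- function(a, prevalence_min = 0.10, mean_abund_min = 1e-4) {
  f <- a$features
  keep <- f$prevalence > prevalence_min & f$mean_abundance > mean_abund_min
  out <- abund_table(a$values[, keep, drop = FALSE], f[keep, , drop = FALSE])
  attr(out, "qc_report") <- tibble::tibble(
    filter = c("prevalence", "mean_abundance"),
    removed = c(sum(f$prevalence <= prevalence_min),
                sum(f$mean_abundance <= mean_abund_min))
  )
  out
}

#' Per-feature pseudocount for log transforms
#'
#' Half the smallest nonzero relative abundance observed for the feature;
#' used to floor zeros before `log10` in the abundance channel and for
#' log-abundance exposures in Mendelian randomization.
#'
#' @param values numeric vector of relative abundances for one feature.
#' @return scalar pseudocount.
#' @export
half_min_pseudocount <- function(values) {
  nz <- values[values > 0]
  if (length(nz) == 0L) abort("feature has no nonzero abundance; cannot form a pseudocount")
  min(nz) / 2
}
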