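#' Genotype dosage container
#'
#' A `geno_matrix` holds a samples x variants dosage matrix (ALT-allele counts
#' in \{0, 1, 2\}, possibly fractional for imputed dosages, `NA` for missing
#' calls) together with per-variant metadata: chromosome, 1-based position,
#' alleles, minor allele frequency, Hardy-Weinberg exact-test p-value and call
#' rate.
#'
#' @param dosage numeric matrix, samples in rows (rownames = sample ids),
#'   variants in columns (colnames = variant ids).
#' @param variants tibble with one row per variant: `variant_id`, `chrom`,
#'   `pos`, `ref`, `alt`. QC statistics are (re)computed on construction.
#' @param subpop optional per-sample subpopulation labels (used by the
#'   simulator and recovered by [genotype_pca()] checks).
#' @return an object of class `geno_matrix`.
#' @export
geno_matrix <- function(dosage, variants = NULL, subpop = NULL) {
  dosage <- as.matrix(dosage)
  if (is.null(rownames(dosage))) {
    rownames(dosage) <- sprintf("S%04d", seq_len(nrow(dosage)))
  }
  if (is.null(colnames(dosage))) {
    colnames(dosage) <- sprintf("var%05d", seq_len(ncol(dosage)))
  }
  if (is.null(variants)) {
    variants <- tibble::tibble(
      variant_id = colnames(dosage),
      chrom = "1",
      pos = seq_len(ncol(dosage)) * 10000L,
      ref = "A",
      alt = "G"
    )
  }
  variants <- tibble::as_tibble(variants)
  if (nrow(variants) != ncol(dosage)) {
    abort("variant table and dosage matrix dimensions disagree")
  }
  if (any(variants$pos < 1)) abort("variant positions must be >= 1 (1-based)")
  g <- structure(
    list(dosage = dosage, variants = variants, subpop = subpop),
    class = "geno_matrix"
  )
  compute_variant_stats(g)
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat(sprintf(
    "<geno_matrix> %d samples x %d variants\n",
    nrow(x$dosage), ncol(x$dosage)
  ))
  print(head(x$variants, 5))
  invisible(x)
}

#' @export
dim.geno_matrix <- function(x) dim(x$dosage)

#' Recompute per-variant QC statistics
#'
#' Minor allele frequency (always folded, so invariant under a REF/ALT swap),
#' call rate, and the Hardy-Weinberg exact-test p-value. HWE is only defined
#' for hard-called dosages; variants with fractional dosages get `NA`.
#'
#' @param g a [geno_matrix()].
#' @return the `geno_matrix` with refreshed `maf`, `hwe_p`, `call_rate`.
#' @export
compute_variant_stats <- function(g) {
  d <- g$dosage
  n <- nrow(d)
  alt_freq <- colMeans(d, na.rm = TRUE) / 2
  call_rate <- 1 - colMeans(is.na(d))
  hwe_p <- vapply(seq_len(ncol(d)), function(j) {
    x <- d[, j]
    x <- x[!is.na(x)]
    if (length(x) == 0L || !all(x %in% c(0, 1, 2))) {
      return(NA_real_)
    }
    hwe_exact_test(sum(x == 0), sum(x == 1), sum(x == 2))
  }, numeric(1))
  g$variants$maf <- unname(pmin(alt_freq, 1 - alt_freq))
  g$variants$call_rate <- unname(call_rate)
  g$variants$hwe_p <- hwe_p
  g
}

#' Subset a genotype matrix by variant
#' @param g a [geno_matrix()].
#' @param keep logical or character index over variants.
#' @return a `geno_matrix` restricted to the selected variants.
#' @export
subset_variants <- function(g, keep) {
  if (is.character(keep)) keep <- match(keep, g$variants$variant_id)
  g$dosage <- g$dosage[, keep, drop = FALSE]
  g$variants <- g$variants[keep, , drop = FALSE]
  g
}

#' Variant-level quality control
#'
#' Keeps variants with MAF >= `maf_min`, HWE exact p > `hwe_min` and call rate
#' > `call_rate_min` — the usual GWAS pre-filters (common variants, no gross
#' genotyping failure). Per-filter removal counts are attached as the
#' `"qc_report"` attribute (a variant can count against several filters).
#'
#' @param g a [geno_matrix()] with QC statistics populated.
#' @param maf_min minimum minor allele frequency (default 0.01).
#' @param hwe_min HWE p-value floor; variants with `hwe_p <= hwe_min` are
#'   dropped (default `1e-6`).
#' @param call_rate_min minimum genotype call rate (default 0.98).
#' @return filtered `geno_matrix`; `attr(, "qc_report")` is a tibble of
#'   per-filter removal counts.
#' @export
variant_qc <- function(g, maf_min = 0.01, hwe_min = 1e-6, call_rate_min = 0.98) {
  v <- g$variants
  fail_maf <- is.na(v$maf) | v$maf < maf_min
  fail_hwe <- !is.na(v$hwe_p) & v$hwe_p <= hwe_min
  fail_cr <- v$call_rate <= call_rate_min
  keep <- !(fail_maf | fail_hwe | fail_cr)
  out <- subset_variants(g, keep)
  attr(out, "qc_report") <- tibble::tibble(
    filter = c("maf", "hwe", "call_rate"),
    removed = c(sum(fail_maf), sum(fail_hwe), sum(fail_cr))
  )
  out
}

#' Mean-impute missing dosages
#'
#' Replaces missing calls by the per-variant mean dosage (the standard
#' fixed-effect GWAS treatment after call-rate filtering). Imputed variants
#' are flagged in the variant table.
#'
#' @param g a [geno_matrix()].
#' @return a `geno_matrix` with no missing dosages and a logical `imputed`
#'   column in `g$variants`.
#' @export
impute_dosage_mean <- function(g) {
  d <- g$dosage
  nmiss <- colSums(is.na(d))
  if (any(nmiss > 0)) {
    mu <- colMeans(d, na.rm = TRUE)
    idx <- which(is.na(d), arr.ind = TRUE)
    d[idx] <- mu[idx[, 2]]
    g$dosage <- d
  }
  g$variants$imputed <- nmiss > 0
  g
}

#' Tidy a genotype matrix's variant metadata
#' @param x a [geno_matrix()].
#' @param ... unused.
#' @return the variant tibble (one row per variant with QC statistics).
#' @method tidy geno_matrix
#' @export
tidy.geno_matrix <- function(x, ...) x$variants
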