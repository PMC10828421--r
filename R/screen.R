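#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment: sort ascending, `adj_i = min_{j >= i}(p_j m / j)`
#' clipped at 1, original order restored (delegates to [stats::p.adjust()]).
#'
#' @param p_values vector of p-values in (0, 1]; may be empty.
#' @return adjusted p-values in the input order.
#' @export
bh_fdr <- function(p_values) {
  if (length(p_values) == 0) return(numeric())
  p.adjust(p_values, method = "BH")
}

#' Two-sided Fisher exact test on a 2x2 table
#'
#' Two-sided p by the probability-mass rule (sum over all tables with the
#' observed margins whose hypergeometric probability does not exceed the
#' observed table's). The sample odds ratio `ad/bc` is reported, not the
#' conditional MLE. A zero row or column margin makes the table
#' uninformative: p = 1 and the odds ratio is missing.
#'
#' @param table 2x2 matrix of non-negative integer counts.
#' @param alternative `"two.sided"` (default), `"greater"`, or `"less"`.
#' @return one-row tibble: `p`, `odds_ratio`.
#' @export
fisher_exact <- function(table, alternative = "two.sided") {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2, 2)) || any(table < 0) ||
      any(table != round(table))) {
    abort("`table` must be a 2x2 matrix of non-negative integer counts")
  }
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    return(tibble::tibble(p = 1, odds_ratio = NA_real_))
  }
  p <- fisher.test(table, alternative = alternative)$p.value
  or <- (table[1, 1] * table[2, 2]) / (table[1, 2] * table[2, 1])
  tibble::tibble(p = p, odds_ratio = or)
}

#' Observational trait-microbe association scan
#'
#' For every feature-trait pair, OLS of the trait on the feature value
#' (log10 relative abundance for AB-channel features, 0/1 presence for
#' PA-channel features) with covariates in-model; BH adjustment is applied
#' jointly across all pairs. By default the covariate roster for this
#' observational scan uses the top four host genetic PCs (the GWAS roster
#' uses ten); pass whatever covariate table is appropriate.
#'
#' @param abundance an [abund_table()].
#' @param traits tibble with `sample_id` and one numeric column per trait.
#' @param covariates covariate tibble.
#' @return tibble: `feature_id`, `trait_id`, `model`, `beta`, `se`, `p`,
#'   `fdr_p`, `n`, `skipped`.
#' @export
trait_microbe_scan <- function(abundance, traits, covariates = NULL) {
  ids <- common_samples(rownames(abundance$values), traits$sample_id,
                        "abundance/traits")
  vals <- abundance$values[ids, , drop = FALSE]
  trait_ids <- setdiff(names(traits), "sample_id")
  trait_mat <- as.matrix(traits[match(ids, traits$sample_id), trait_ids])
  rows <- purrr::map(colnames(vals), function(f) {
    x <- vals[, f]
    prev <- mean(x > 0)
    model <- choose_model(prev)
    xv <- if (model == "AB") {
      log10(pmax(x, half_min_pseudocount(x)))
    } else {
      as.numeric(x > 0)
    }
    names(xv) <- ids
    purrr::map(trait_ids, function(tr) {
      y <- trait_mat[, tr]
      if (var(y) < 1e-12) {
        return(tibble::tibble(
          feature_id = f, trait_id = tr, model = model, beta = NA_real_,
          se = NA_real_, p = NA_real_, n = length(y), skipped = TRUE
        ))
      }
      fit <- covariate_adjusted_assoc(xv, y, covariates)
      tibble::tibble(
        feature_id = f, trait_id = tr, model = model, beta = fit$beta,
        se = fit$se, p = fit$p, n = fit$n, skipped = FALSE
      )
    }) |> dplyr::bind_rows()
  })
  out <- dplyr::bind_rows(rows)
  out$fdr_p <- NA_real_
  out$fdr_p[!out$skipped] <- bh_fdr(out$p[!out$skipped])
  dplyr::relocate(out, "fdr_p", .after = "p")
}

#' Fisher-exact PheWAS enrichment of microbiome-associated variants
#'
#' For each trait, a 2x2 table of (MAV vs background variant) x
#' (trait-associated vs not) is tested with [fisher_exact()]; BH adjustment
#' across traits. The background universe of variants must be supplied
#' explicitly.
#'
#' @param assoc_matrix logical/0-1 matrix, variants x traits: is the variant
#'   associated with the trait (rownames = variant ids).
#' @param mav_ids character vector of microbiome-associated variant ids
#'   (non-empty, all in the universe).
#' @param universe character vector of all background variant ids (default:
#'   rownames of `assoc_matrix`).
#' @return tibble per trait: `trait_id`, the 2x2 counts `a` (MAV &
#'   associated), `b` (MAV & not), `c` (background & associated), `d`
#'   (background & not), `odds_ratio`, `p`, `fdr_p`; traits with no
#'   associated variants anywhere are skipped.
#' @export
phewas_enrichment <- function(assoc_matrix, mav_ids,
                              universe = rownames(assoc_matrix)) {
  if (length(mav_ids) == 0) abort("`mav_ids` must be non-empty")
  assoc_matrix <- as.matrix(assoc_matrix) > 0
  if (is.null(rownames(assoc_matrix))) {
    abort("`assoc_matrix` must have variant ids as rownames")
  }
  missing <- setdiff(mav_ids, universe)
  if (length(missing) > 0) {
    abort(sprintf("MAVs outside the universe: %s",
                  paste(missing, collapse = ", ")))
  }
  bg <- setdiff(universe, mav_ids)
  rows <- purrr::map(colnames(assoc_matrix), function(tr) {
    hits <- rownames(assoc_matrix)[assoc_matrix[, tr]]
    if (length(intersect(hits, universe)) == 0) return(NULL)
    a <- length(intersect(mav_ids, hits))
    b <- length(mav_ids) - a
    cc <- length(intersect(bg, hits))
    dd <- length(bg) - cc
    ft <- fisher_exact(matrix(c(a, cc, b, dd), 2))
    tibble::tibble(trait_id = tr, a = a, b = b, c = cc, d = dd,
                   odds_ratio = ft$odds_ratio, p = ft$p)
  })
  out <- dplyr::bind_rows(purrr::compact(rows))
  if (nrow(out) > 0) out$fdr_p <- bh_fdr(out$p)
  out
}
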