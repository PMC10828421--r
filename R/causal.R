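#' Select clumped genetic instruments for an exposure
#'
#' Variants below `p_max` in the exposure's summary statistics are greedily
#' clumped (ascending p, LD `r^2 < ld_r2` between surviving indices within
#' `window_bp`); the clump indices form the instrument set. Each instrument
#' is oriented so that its effect allele increases the exposure (a negative
#' GWAS beta flips the orientation to the REF allele).
#'
#' @param sumstats tibble with `variant_id`, `beta`, `p` for the exposure.
#' @param g a [geno_matrix()] with the dosages for LD.
#' @param p_max instrument selection threshold (default `1e-6`).
#' @param ld_r2 clumping LD threshold (default 0.1).
#' @param window_bp clumping window (default 1 Mb).
#' @return tibble: `variant_id`, `p`, `beta`, `orientation` (+1 if the ALT
#'   allele increases the exposure, -1 otherwise). Empty (zero rows) when no
#'   variant passes `p_max`.
#' @export
select_instruments <- function(sumstats, g, p_max = 1e-6, ld_r2 = 0.1,
                               window_bp = 1e6) {
  empty <- tibble::tibble(variant_id = character(), p = numeric(),
                          beta = numeric(), orientation = numeric())
  hits <- dplyr::filter(sumstats, !is.na(.data$p), .data$p < p_max)
  if (nrow(hits) == 0) return(empty)
  clumps <- clump_loci(hits, g, window_bp = window_bp, r2 = ld_r2,
                       p_max = p_max)
  if (nrow(clumps) == 0) return(empty)
  iv <- dplyr::left_join(
    clumps[c("index_id", "index_p")],
    dplyr::group_by(hits, .data$variant_id) |>
      dplyr::slice_min(.data$p, n = 1, with_ties = FALSE) |>
      dplyr::ungroup() |>
      dplyr::select("variant_id", "beta"),
    by = c(index_id = "variant_id")
  )
  tibble::tibble(
    variant_id = iv$index_id, p = iv$index_p, beta = iv$beta,
    orientation = ifelse(iv$beta >= 0, 1, -1)
  )
}

#' Unweighted genetic risk score
#'
#' Per-sample sum of exposure-increasing allele counts over the instrument
#' set: dosage `d` for a +1-oriented instrument, `2 - d` for a -1-oriented
#' one. Integer-valued for hard calls.
#'
#' @param g a [geno_matrix()].
#' @param iv instrument tibble from [select_instruments()].
#' @return named numeric score per sample.
#' @export
grs <- function(g, iv) {
  missing <- setdiff(iv$variant_id, colnames(g$dosage))
  if (length(missing) > 0) {
    abort(sprintf("instrument variants absent from genotypes: %s",
                  paste(missing, collapse = ", ")))
  }
  D <- g$dosage[, iv$variant_id, drop = FALSE]
  oriented <- sweep(D, 2, iv$orientation, "*") +
    matrix(rep(ifelse(iv$orientation < 0, 2, 0), each = nrow(D)), nrow(D))
  rowSums(oriented)
}

#' Two-stage least squares causal estimate
#'
#' Stage 1 regresses the exposure on `[1, score, covariates]` (recording the
#' partial F of the score and the exposure variance it explains); stage 2
#' regresses the outcome on `[1, fitted exposure, covariates]`. The standard
#' error uses the proper TSLS residual — outcome minus the stage-2
#' coefficients applied to the observed exposure — not the naive stage-2 OLS
#' residual. A partial F below 10 raises the weak-instrument flag (the
#' estimate is still returned).
#'
#' @param exposure,outcome,score aligned numeric vectors.
#' @param covariates optional covariate tibble or matrix.
#' @return one-row tibble: `beta`, `se`, `statistic`, `p`, `first_stage_f`,
#'   `r2_instrument`, `n`, `weak_instrument`.
#' @export
tsls <- function(exposure, outcome, score, covariates = NULL) {
  ids <- names(exposure) %||% names(score)
  C <- if (is.null(covariates)) NULL else covariate_matrix(covariates, ids)
  n <- length(exposure)
  p_cov <- if (is.null(C)) 0 else ncol(C)
  if (n <= p_cov + 3) abort("too few samples for TSLS")
  if (var(score) < 1e-12) abort("instrument score has zero variance")
  # stage 1
  X1 <- cbind(1, score, C)
  f1 <- lm.fit(X1, exposure)
  df1 <- n - ncol(X1)
  sigma1 <- sum(f1$residuals^2) / df1
  XtXinv1 <- chol2inv(qr.R(qr(X1)))
  t1 <- f1$coefficients[2] / sqrt(sigma1 * XtXinv1[2, 2])
  first_stage_f <- t1^2
  # partial R2 of the score given covariates
  e_red <- drop(residualize_on(exposure, C))
  r2_instrument <- 1 - sum(f1$residuals^2) / sum(e_red^2)
  fitted_exposure <- f1$fitted.values
  # stage 2 on the fitted exposure
  X2 <- cbind(1, fitted_exposure, C)
  f2 <- lm.fit(X2, outcome)
  beta <- f2$coefficients[2]
  # proper TSLS residual: stage-2 coefficients applied to observed exposure
  X2_obs <- cbind(1, exposure, C)
  resid_iv <- outcome - drop(X2_obs %*% f2$coefficients)
  df2 <- n - ncol(X2)
  sigma_iv <- sum(resid_iv^2) / df2
  XtXinv2 <- chol2inv(qr.R(qr(X2)))
  se <- sqrt(sigma_iv * XtXinv2[2, 2])
  stat <- beta / se
  tibble::tibble(
    beta = beta, se = se, statistic = stat, p = 2 * pt(-abs(stat), df2),
    first_stage_f = as.numeric(first_stage_f),
    r2_instrument = r2_instrument, n = n,
    weak_instrument = first_stage_f < 10
  )
}

#' Bidirectional one-sample Mendelian randomization
#'
#' Runs [select_instruments()], [grs()] and [tsls()] in each causal
#' direction for one feature-trait pair. Exposures enter on the scale used
#' in their GWAS: log10 relative abundance for AB-channel features (zeros
#' floored at the half-minimum pseudocount), the 0/1 presence indicator in a
#' linear-probability first stage for PA-channel features. A direction with
#' no instruments is marked not-estimable rather than raising an error.
#'
#' @param feature_values named relative abundances of the microbial feature.
#' @param trait_values named numeric trait values.
#' @param feature_sumstats,trait_sumstats per-variant GWAS summary tibbles
#'   (`variant_id`, `beta`, `p`) for the feature and the trait.
#' @param g a [geno_matrix()].
#' @param covariates covariate tibble.
#' @param p_max,ld_r2 instrument selection parameters.
#' @param n_pairs batch size for the reported Bonferroni threshold
#'   (default 1).
#' @return tibble with one row per direction: `direction`, `estimable`,
#'   `n_iv`, and the [tsls()] columns; `attr(, "bonferroni_threshold")` is
#'   `0.05 / n_pairs`.
#' @export
bidirectional_mr <- function(feature_values, trait_values, feature_sumstats,
                             trait_sumstats, g, covariates = NULL,
                             p_max = 1e-6, ld_r2 = 0.1, n_pairs = 1) {
  ids <- common_samples(names(feature_values), rownames(g$dosage),
                        "feature/genotypes")
  x_feat <- feature_values[ids]
  prev <- mean(x_feat > 0)
  exposure_feat <- if (prev > 0.95) {
    log10(pmax(x_feat, half_min_pseudocount(x_feat)))
  } else {
    as.numeric(x_feat > 0)
  }
  names(exposure_feat) <- ids
  y_trait <- trait_values[ids]
  one_direction <- function(direction, exposure, outcome, sumstats) {
    iv <- select_instruments(sumstats, g, p_max = p_max, ld_r2 = ld_r2)
    if (nrow(iv) == 0) {
      return(tibble::tibble(
        direction = direction, estimable = FALSE, n_iv = 0L,
        beta = NA_real_, se = NA_real_, statistic = NA_real_, p = NA_real_,
        first_stage_f = NA_real_, r2_instrument = NA_real_,
        n = length(exposure), weak_instrument = NA
      ))
    }
    score <- grs(g, iv)[ids]
    est <- tsls(exposure, outcome, score, covariates)
    dplyr::bind_cols(
      tibble::tibble(direction = direction, estimable = TRUE,
                     n_iv = nrow(iv)),
      est
    )
  }
  out <- dplyr::bind_rows(
    one_direction("feature->trait", exposure_feat, y_trait, feature_sumstats),
    one_direction("trait->feature", y_trait, exposure_feat, trait_sumstats)
  )
  attr(out, "bonferroni_threshold") <- bonferroni_threshold(0.05, n_pairs)
  out
}
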