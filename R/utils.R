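#' @importFrom rlang abort warn %||% .data
#' @importFrom stats pchisq pf pnorm pt qchisq rbeta rbinom rlnorm rnorm runif
#' @importFrom stats coef complete.cases cor fisher.test glm.fit lm.fit median
#' @importFrom stats p.adjust plogis qlogis quantile sd setNames t.test var
#' @importFrom stats wilcox.test binomial
#' @importFrom utils head
NULL

# shared sample ids, in the order of the first argument
common_samples <- function(a, b, what = "inputs") {
  ids <- intersect(a, b)
  if (length(ids) == 0L) {
    abort(sprintf("no shared sample ids between %s (keyed join failed)", what))
  }
  ids
}

stopifnot_scalar_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    abort(sprintf("`%s` must be a single probability in [0, 1]", name))
  }
}

# numeric covariate design (no intercept) aligned to `sample_ids`
covariate_matrix <- function(covariates, sample_ids = NULL) {
  if (is.null(covariates)) {
    return(NULL)
  }
  if (is.matrix(covariates)) {
    m <- covariates
  } else {
    covariates <- tibble::as_tibble(covariates)
    if (!"sample_id" %in% names(covariates)) {
      abort("covariate table must have a `sample_id` column")
    }
    m <- as.matrix(covariates[setdiff(names(covariates), "sample_id")])
    rownames(m) <- covariates$sample_id
  }
  if (!is.numeric(m)) abort("covariates must be numeric")
  if (!is.null(sample_ids)) {
    missing <- setdiff(sample_ids, rownames(m))
    if (length(missing) > 0) {
      abort(sprintf(
        "covariates missing for %d sample(s), e.g. %s",
        length(missing), missing[1]
      ))
    }
    m <- m[sample_ids, , drop = FALSE]
  }
  if (anyNA(m)) abort("covariates contain missing values after join")
  m
}

# residualize columns of `x` on [1, C] via QR; returns matrix.
# strict = TRUE errors on a rank-deficient design; strict = FALSE tolerates
# it (the projection is still well-defined via the pivoted QR)
residualize_on <- function(x, C = NULL, strict = TRUE) {
  x <- as.matrix(x)
  X <- if (is.null(C)) matrix(1, nrow(x), 1) else cbind(1, C)
  qr_X <- qr(X)
  if (strict && qr_X$rank < ncol(X)) {
    bad <- colnames(X)[-seq_len(qr_X$rank)] %||% "unknown"
    abort(sprintf("rank-deficient covariate design (collinear: %s)",
                  paste(bad, collapse = ", ")))
  }
  x - qr.fitted(qr_X, x)
}

#' @export
generics::tidy

#' @export
generics::glance

#' @export
ggplot2::autoplot
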