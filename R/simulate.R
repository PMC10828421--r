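#' Synthetic cohort configuration
#'
#' Parameters of the synthetic genotype-microbiome-trait cohort generator.
#' The generator emulates the statistical structure the M-GWAS analysis
#' assumes: two subpopulations in Hardy-Weinberg equilibrium within
#' subpopulation (Balding-Nichols allele-frequency model), compositional taxa
#' abundances with a prevalence spectrum spanning core (>95%) and
#' intermediate (10-95%) features, planted additive SNP effects on latent
#' log-abundance (AB channel) or on presence log-odds (PA channel), and host
#' traits with confounded taxon-to-trait causal effects for which the planted
#' SNPs are valid instruments.
#'
#' @param n_samples,n_variants,n_taxa,n_traits cohort dimensions.
#' @param fst Balding-Nichols divergence parameter in [0, 1); subpopulation
#'   allele frequencies are drawn from
#'   `Beta(p(1-F)/F, (1-p)(1-F)/F)` around the ancestral frequency `p`
#'   (F = 0 means both subpopulations share `p`). Default 0.01, a mild
#'   north/south-style structure.
#' @param maf_range ancestral allele-frequency range, within (0, 0.5].
#' @param subpop_fractions pair summing to 1.
#' @param effect_table tibble of planted SNP effects with columns `variant`
#'   (index), `taxon` (index), `beta` (per ALT-allele effect on latent
#'   log-abundance, or on presence log-odds), `channel` (`"AB"` or `"PA"`).
#' @param causal_table tibble of taxon-to-trait causal effects with columns
#'   `taxon`, `trait`, `alpha` (effect per unit log10-abundance),
#'   `load_taxon`, `load_trait` (loadings of a shared latent confounder
#'   `U ~ N(0, 1)` on the taxon's latent abundance and on the trait).
#' @param noise_sd residual SD of the latent log-abundance (default 1).
#' @param seed integer seed; a fixed config yields byte-identical outputs.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_samples = 500, n_variants = 1000, n_taxa = 50,
                       n_traits = 5, fst = 0.01, maf_range = c(0.05, 0.5),
                       subpop_fractions = c(0.5, 0.5),
                       effect_table = NULL, causal_table = NULL,
                       noise_sd = 1, seed = 1) {
  if (fst < 0 || fst >= 1) abort("`fst` must be in [0, 1)")
  if (length(maf_range) != 2L || any(maf_range <= 0) || any(maf_range > 0.5) ||
      maf_range[1] > maf_range[2]) {
    abort("`maf_range` must be an increasing pair within (0, 0.5]")
  }
  if (abs(sum(subpop_fractions) - 1) > 1e-8 || length(subpop_fractions) != 2L) {
    abort("`subpop_fractions` must be a pair summing to 1")
  }
  if (noise_sd <= 0) abort("`noise_sd` must be positive")
  effect_table <- if (is.null(effect_table)) {
    tibble::tibble(variant = integer(), taxon = integer(),
                   beta = numeric(), channel = character())
  } else tibble::as_tibble(effect_table)
  causal_table <- if (is.null(causal_table)) {
    tibble::tibble(taxon = integer(), trait = integer(), alpha = numeric(),
                   load_taxon = numeric(), load_trait = numeric())
  } else tibble::as_tibble(causal_table)
  if (nrow(effect_table) > 0) {
    if (any(effect_table$variant < 1 | effect_table$variant > n_variants) ||
        any(effect_table$taxon < 1 | effect_table$taxon > n_taxa) ||
        !all(effect_table$channel %in% c("AB", "PA"))) {
      abort("effect_table indices or channels out of range")
    }
  }
  if (nrow(causal_table) > 0) {
    if (any(causal_table$taxon < 1 | causal_table$taxon > n_taxa) ||
        any(causal_table$trait < 1 | causal_table$trait > n_traits)) {
      abort("causal_table indices out of range")
    }
  }
  structure(list(
    n_samples = n_samples, n_variants = n_variants, n_taxa = n_taxa,
    n_traits = n_traits, fst = fst, maf_range = maf_range,
    subpop_fractions = subpop_fractions, effect_table = effect_table,
    causal_table = causal_table, noise_sd = noise_sd, seed = as.integer(seed)
  ), class = "sim_config")
}

#' Simulate two-subpopulation genotypes
#'
#' Balding-Nichols model: per variant, an ancestral frequency
#' `p ~ Uniform(maf_range)`; each subpopulation's frequency is drawn from
#' `Beta(p(1-F)/F, (1-p)(1-F)/F)`; genotypes are `Binomial(2, freq)`, so HWE
#' holds by construction within subpopulation. Variants are laid out every
#' 10 kb along one chromosome so that distance-window operations (clumping)
#' are exercised.
#'
#' @param config a [sim_config()].
#' @return a [geno_matrix()] with a `subpop` label per sample.
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_samples
  m <- config$n_variants
  n1 <- round(n * config$subpop_fractions[1])
  subpop <- rep(c("pop1", "pop2"), c(n1, n - n1))
  p <- runif(m, config$maf_range[1], config$maf_range[2])
  if (config$fst > 0) {
    a <- p * (1 - config$fst) / config$fst
    b <- (1 - p) * (1 - config$fst) / config$fst
    f1 <- rbeta(m, a, b)
    f2 <- rbeta(m, a, b)
  } else {
    f1 <- f2 <- p
  }
  d1 <- matrix(rbinom(n1 * m, 2, rep(f1, each = n1)), nrow = n1)
  d2 <- matrix(rbinom((n - n1) * m, 2, rep(f2, each = n - n1)), nrow = n - n1)
  d <- rbind(d1, d2)
  rownames(d) <- sprintf("S%04d", seq_len(n))
  colnames(d) <- sprintf("var%05d", seq_len(m))
  g <- geno_matrix(d, subpop = setNames(subpop, rownames(d)))
  g
}

#' Simulate host covariates
#'
#' Age ~ N(30, 5) and sex ~ Bernoulli(0.63) match the cohort profile the
#' analysis is designed for (mean age 30, 63% female); BMI ~ N(22, 3);
#' sequencing read count ~ LogNormal around 5e7 reads.
#'
#' @param config a [sim_config()].
#' @return a tibble: `sample_id`, `age`, `sex`, `bmi`, `read_count`.
#' @export
simulate_covariates <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  n <- config$n_samples
  tibble::tibble(
    sample_id = sprintf("S%04d", seq_len(n)),
    age = rnorm(n, 30, 5),
    sex = rbinom(n, 1, 0.63),
    bmi = rnorm(n, 22, 3),
    read_count = rlnorm(n, log(5e7), 0.3)
  )
}

# shared latent confounder; regenerated deterministically so that
# simulate_microbiome and simulate_traits agree when called separately
sim_confounder <- function(config) {
  set.seed(config$seed + 2L)
  rnorm(config$n_samples)
}

#' Simulate compositional microbiome abundances
#'
#' A hurdle (two-part) model per taxon: a latent log-abundance
#' `a_ij = mu_j + sum_k beta_jk g_ik + covariate terms + subpop shift +
#' confounder loading + N(0, noise_sd^2)`, and a presence indicator with
#' log-odds `logit(prev_j) + planted PA effects`. Present values are
#' exponentiated and each sample's row is closed (divided by its sum), so
#' rows sum to 1. Roughly 30% of taxa are "core" (target prevalence 98%,
#' landing in the AB channel); the rest span prevalences 0.15-0.90 (PA
#' channel).
#'
#' @param genotypes a [geno_matrix()] from [simulate_genotypes()].
#' @param covariates tibble from [simulate_covariates()].
#' @param config the same [sim_config()].
#' @return an [abund_table()].
#' @export
simulate_microbiome <- function(genotypes, covariates, config) {
  stopifnot(inherits(config, "sim_config"))
  ids <- rownames(genotypes$dosage)
  if (!setequal(ids, covariates$sample_id)) {
    abort("genotype and covariate sample ids do not match (keyed join failed)")
  }
  C <- covariate_matrix(covariates, ids)
  Cs <- scale(C)
  U <- sim_confounder(config)
  set.seed(config$seed + 3L)
  n <- config$n_samples
  Tx <- config$n_taxa
  n_core <- max(1L, round(0.3 * Tx))
  prev_target <- c(rep(0.98, n_core),
                   seq(0.15, 0.90, length.out = Tx - n_core))
  mu <- rnorm(Tx, 0, 1)
  B_cov <- matrix(rnorm(Tx * ncol(Cs), 0, 0.05), ncol(Cs), Tx)
  pop_shift <- rnorm(Tx, 0, 0.3)
  pop_ind <- as.numeric(genotypes$subpop[ids] == "pop2")
  if (length(pop_ind) == 0 || anyNA(pop_ind)) pop_ind <- rep(0, n)

  A <- matrix(rep(mu, each = n), n, Tx) + Cs %*% B_cov +
    outer(pop_ind, pop_shift) + matrix(rnorm(n * Tx, 0, config$noise_sd), n, Tx)
  eta <- matrix(rep(qlogis(prev_target), each = n), n, Tx)
  eff <- config$effect_table
  for (i in seq_len(nrow(eff))) {
    gvec <- genotypes$dosage[ids, eff$variant[i]]
    if (eff$channel[i] == "AB") {
      A[, eff$taxon[i]] <- A[, eff$taxon[i]] + eff$beta[i] * gvec
    } else {
      eta[, eff$taxon[i]] <- eta[, eff$taxon[i]] + eff$beta[i] * gvec
    }
  }
  for (i in seq_len(nrow(config$causal_table))) {
    tx <- config$causal_table$taxon[i]
    A[, tx] <- A[, tx] + config$causal_table$load_taxon[i] * U
  }
  present <- matrix(rbinom(n * Tx, 1, plogis(eta)), n, Tx)
  vals <- present * exp(A)
  # guard against an (astronomically rare) all-absent sample
  empty <- rowSums(vals) == 0
  if (any(empty)) {
    jmax <- apply(A[empty, , drop = FALSE], 1, which.max)
    vals[cbind(which(empty), jmax)] <- exp(A[cbind(which(empty), jmax)])
  }
  vals <- vals / rowSums(vals)
  rownames(vals) <- ids
  colnames(vals) <- sprintf("t%03d", seq_len(Tx))
  features <- tibble::tibble(
    feature_id = colnames(vals),
    clade_name = sprintf("k__Bacteria|p__P%02d|g__Genus%03d|s__Species%03d",
                         (seq_len(Tx) %% 8) + 1, seq_len(Tx), seq_len(Tx))
  )
  abund_table(vals, features)
}

#' Simulate host traits with confounded causal taxon effects
#'
#' Each trait is `sum alpha * log10(abundance)` over its causal taxa plus the
#' shared latent confounder (loading `load_trait`), small covariate terms and
#' unit-variance noise. Because the confounder also loads on the taxon's
#' latent abundance, the naive taxon-trait regression is biased, while the
#' planted SNPs (which affect the taxon only) remain valid instruments —
#' there is no direct SNP-to-trait path. Zero abundances are floored at the
#' per-taxon half-minimum pseudocount before the log.
#'
#' @param abundance [abund_table()] from [simulate_microbiome()].
#' @param covariates tibble from [simulate_covariates()].
#' @param config the same [sim_config()].
#' @return a list: `traits` (tibble `sample_id`, `trait_1`...) and `truth`
#'   (planted effects, causal effects, per-sample confounder).
#' @export
simulate_traits <- function(abundance, covariates, config) {
  stopifnot(inherits(config, "sim_config"))
  ids <- rownames(abundance$values)
  C <- covariate_matrix(covariates, ids)
  Cs <- scale(C)
  U <- sim_confounder(config)
  set.seed(config$seed + 4L)
  n <- config$n_samples
  K <- config$n_traits
  B_cov <- matrix(rnorm(K * ncol(Cs), 0, 0.05), ncol(Cs), K)
  Y <- Cs %*% B_cov + matrix(rnorm(n * K), n, K)
  for (i in seq_len(nrow(config$causal_table))) {
    row <- config$causal_table[i, ]
    x <- abundance$values[, row$taxon]
    logx <- log10(pmax(x, half_min_pseudocount(x)))
    Y[, row$trait] <- Y[, row$trait] + row$alpha * logx + row$load_trait * U
  }
  colnames(Y) <- sprintf("trait_%d", seq_len(K))
  traits <- dplyr::bind_cols(tibble::tibble(sample_id = ids),
                             tibble::as_tibble(Y))
  list(
    traits = traits,
    truth = list(
      planted_effects = config$effect_table,
      causal_effects = config$causal_table,
      confounder = setNames(U, ids)
    )
  )
}

#' Simulate a full synthetic cohort
#'
#' Runs [simulate_genotypes()], [simulate_covariates()],
#' [simulate_microbiome()] and [simulate_traits()] and collects the truth
#' table for parameter-recovery tests.
#'
#' @param config a [sim_config()].
#' @return list: `genotypes`, `covariates`, `abundance`, `traits`, `truth`.
#' @export
simulate_cohort <- function(config) {
  g <- simulate_genotypes(config)
  cv <- simulate_covariates(config)
  a <- simulate_microbiome(g, cv, config)
  tt <- simulate_traits(a, cv, config)
  tt$truth$subpop <- g$subpop
  list(genotypes = g, covariates = cv, abundance = a,
       traits = tt$traits, truth = tt$truth)
}

#' Write a simulated cohort to disk
#'
#' Emits `genotypes.vcf`, `abundance.tsv` (MetaPhlAn style), `covariates.tsv`,
#' `traits.tsv` and `truth.tsv` under `dir`.
#'
#' @param cohort output of [simulate_cohort()].
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_vcf(cohort$genotypes, file.path(dir, "genotypes.vcf"))
  write_abundance(cohort$abundance, file.path(dir, "abundance.tsv"))
  readr::write_tsv(cohort$covariates, file.path(dir, "covariates.tsv"),
                   progress = FALSE)
  readr::write_tsv(cohort$traits, file.path(dir, "traits.tsv"),
                   progress = FALSE)
  truth <- dplyr::bind_rows(
    dplyr::mutate(cohort$truth$planted_effects, kind = "planted_snp_effect"),
    dplyr::mutate(cohort$truth$causal_effects, kind = "causal_effect")
  )
  readr::write_tsv(truth, file.path(dir, "truth.tsv"), progress = FALSE)
  invisible(dir)
}
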