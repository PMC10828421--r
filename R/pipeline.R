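#' Pipeline configuration
#'
#' Collects inputs (paths or in-memory objects) and all analysis thresholds
#' with defaults matching standard M-GWAS practice: MAF >= 0.01, HWE p >
#' 1e-6, call rate > 0.98, feature prevalence > 0.10 and mean abundance >
#' 1e-4, decorrelation edge threshold 0.995, genome-wide alpha 5e-8, 1 Mb /
#' r^2 0.2 clumping, MR instrument p < 1e-6 with r^2 < 0.1 clumping.
#'
#' @param genotypes [geno_matrix()] or path (VCF / dosage TSV).
#' @param abundance [abund_table()] or path (MetaPhlAn-style TSV).
#' @param covariates covariate tibble or TSV path (`sample_id` first
#'   column); host genetic PCs are added by the pipeline.
#' @param traits optional trait tibble or TSV path; enables the
#'   observational scan and MR stages.
#' @param out_dir optional output directory; when given, all stage tables
#'   are written as TSV plus a JSON run report.
#' @param maf_min,hwe_min,call_rate_min variant QC thresholds.
#' @param prevalence_min,mean_abund_min feature QC thresholds.
#' @param edge_threshold feature decorrelation threshold.
#' @param n_pcs_gwas,n_pcs_scan host PCs used as GWAS / observational-scan
#'   covariates.
#' @param alpha_gw genome-wide significance level.
#' @param clump_window_bp,clump_r2 locus clumping parameters.
#' @param mr_p_max,mr_ld_r2 MR instrument selection parameters.
#' @param n_perm permutations for the variance-partition null (0 disables
#'   the stage).
#' @param n_top lead loci carried into the variance model.
#' @param seed integer seed for every stochastic step.
#' @return a `run_config` list.
#' @export
run_config <- function(genotypes, abundance, covariates, traits = NULL,
                       out_dir = NULL,
                       maf_min = 0.01, hwe_min = 1e-6, call_rate_min = 0.98,
                       prevalence_min = 0.10, mean_abund_min = 1e-4,
                       edge_threshold = 0.995,
                       n_pcs_gwas = 10, n_pcs_scan = 4,
                       alpha_gw = 5e-8,
                       clump_window_bp = 1e6, clump_r2 = 0.2,
                       mr_p_max = 1e-6, mr_ld_r2 = 0.1,
                       n_perm = 0, n_top = 21, seed = 1) {
  structure(as.list(environment()), class = "run_config")
}

#' Run the full M-GWAS pipeline
#'
#' Stage order: variant/feature QC -> diversity and ordination (genotype PCA
#' supplies the host PC covariates) -> greedy feature decorrelation ->
#' GWAS (per-feature AB/PA channels, Shannon/Simpson, top PCos, beta-diversity
#' MANOVA) -> locus clumping and Bonferroni thresholds -> optional
#' variance-partition permutation null -> optional observational trait scan.
#' Returns all stage tables; when `out_dir` is set, writes them as TSV with
#' a JSON report (config echo, per-stage counts, per-feature inflation).
#'
#' @param config a [run_config()].
#' @return named list of stage outputs, invisibly when written to disk.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  g <- config$genotypes
  if (is.character(g)) g <- read_genotypes(g)
  a <- config$abundance
  if (is.character(a)) a <- read_abundance(a)
  cv <- config$covariates
  if (is.character(cv)) cv <- read_sample_table(cv)
  traits <- config$traits
  if (is.character(traits)) traits <- read_sample_table(traits)

  ids <- common_samples(rownames(g$dosage), rownames(a$values))
  ids <- common_samples(ids, cv$sample_id, "genotypes/covariates")
  g$dosage <- g$dosage[ids, , drop = FALSE]
  g <- compute_variant_stats(g)
  a <- abund_table(a$values[ids, , drop = FALSE], a$features)
  cv <- cv[match(ids, cv$sample_id), , drop = FALSE]
  if (!is.null(traits)) {
    traits <- traits[match(ids, traits$sample_id), , drop = FALSE]
  }

  # --- QC ---
  n_var_in <- ncol(g$dosage)
  g <- variant_qc(g, config$maf_min, config$hwe_min, config$call_rate_min)
  variant_report <- attr(g, "qc_report")
  g <- impute_dosage_mean(g)
  n_feat_in <- ncol(a$values)
  a <- feature_qc(a, config$prevalence_min, config$mean_abund_min)
  feature_report <- attr(a, "qc_report")

  # --- diversity / ordination ---
  alpha <- alpha_diversity(a)
  bc <- bray_curtis(a)
  pco <- pcoa(bc, k = config$n_pcs_gwas)
  pca <- genotype_pca(g, k = config$n_pcs_gwas)
  pcs <- tidy.ordination(pca)
  gwas_cov <- dplyr::inner_join(cv, pcs, by = "sample_id")
  scan_cov <- dplyr::select(
    gwas_cov,
    dplyr::all_of(c(setdiff(names(cv), "sample_id")[
      seq_len(min(4, ncol(cv) - 1))
    ], "sample_id",
    sprintf("PC%d", seq_len(min(config$n_pcs_scan, config$n_pcs_gwas)))))
  )

  # host PC vs diversity/composition associations
  shannon <- setNames(alpha$shannon, alpha$sample_id)
  pc_assoc <- purrr::map(colnames(pca$coordinates), function(pc) {
    x <- setNames(pcs[[pc]], pcs$sample_id)
    dplyr::bind_rows(
      dplyr::mutate(
        covariate_adjusted_assoc(x, shannon[names(x)], cv),
        pc = pc, response = "shannon"
      ),
      purrr::map(colnames(pco$coordinates), function(ax) {
        y <- setNames(pco$coordinates[, ax], rownames(pco$coordinates))
        dplyr::mutate(covariate_adjusted_assoc(x, y[names(x)], cv),
                      pc = pc, response = ax)
      }) |> dplyr::bind_rows()
    )
  }) |> dplyr::bind_rows()

  # --- feature decorrelation ---
  sel <- greedy_representatives(a, threshold = config$edge_threshold,
                                seed = config$seed)

  # --- GWAS ---
  sumstats <- feature_gwas(a, g, gwas_cov, features = sel$kept)
  inflation <- gwas_inflation(sumstats)
  diversity_stats <- dplyr::bind_rows(
    dplyr::mutate(diversity_gwas(shannon, g, gwas_cov),
                  phenotype = "shannon"),
    purrr::map(colnames(pco$coordinates), function(ax) {
      y <- setNames(pco$coordinates[, ax], rownames(pco$coordinates))
      dplyr::mutate(diversity_gwas(y, g, gwas_cov), phenotype = ax)
    }) |> dplyr::bind_rows()
  )
  beta_manova <- manova_beta_gwas(pco, g, gwas_cov)

  study_wide <- bonferroni_threshold(config$alpha_gw, length(sel$kept))
  clumps <- clump_loci(sumstats, g, window_bp = config$clump_window_bp,
                       r2 = config$clump_r2, p_max = config$alpha_gw)

  # --- variance partition ---
  varpart <- if (config$n_perm > 0) {
    snp_variance_permutation_null(
      a, g, gwas_cov, n_top = config$n_top, n_perm = config$n_perm,
      seed = config$seed, clump_r2 = config$clump_r2,
      clump_window_bp = config$clump_window_bp
    )
  }

  # --- observational scan ---
  scan <- if (!is.null(traits)) {
    trait_microbe_scan(a, traits, scan_cov)
  }

  out <- list(
    genotypes = g, abundance = a, covariates = gwas_cov,
    alpha = alpha, pcoa = pco, pca = pca, pc_assoc = pc_assoc,
    selection = sel, sumstats = sumstats, inflation = inflation,
    diversity_stats = diversity_stats, beta_manova = beta_manova,
    clumps = clumps, study_wide_threshold = study_wide,
    varpart = varpart, scan = scan,
    report = list(
      seed = config$seed,
      n_samples = length(ids),
      variants = list(input = n_var_in, kept = ncol(g$dosage),
                      removed = as.list(setNames(variant_report$removed,
                                                 variant_report$filter))),
      features = list(input = n_feat_in, after_qc = ncol(a$values),
                      kept = length(sel$kept),
                      removed = as.list(setNames(feature_report$removed,
                                                 feature_report$filter))),
      lambda_gc = list(min = suppressWarnings(min(inflation$lambda_gc, na.rm = TRUE)),
                       median = median(inflation$lambda_gc, na.rm = TRUE),
                       max = suppressWarnings(max(inflation$lambda_gc, na.rm = TRUE))),
      n_clumps = nrow(clumps),
      study_wide_threshold = study_wide
    )
  )
  if (!is.null(config$out_dir)) {
    write_pipeline_outputs(out, config)
  }
  out
}

write_pipeline_outputs <- function(out, config) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(x, name) {
    readr::write_tsv(x, file.path(config$out_dir, name), progress = FALSE)
  }
  w(out$alpha, "alpha.tsv")
  w(tidy.ordination(out$pcoa), "pcoa.tsv")
  w(out$pc_assoc, "pc_assoc.tsv")
  w(out$selection$map, "feature_map.tsv")
  w(out$sumstats, "sumstats.tsv")
  w(out$inflation, "lambda_gc.tsv")
  w(out$diversity_stats, "diversity_sumstats.tsv")
  w(out$beta_manova, "beta_manova.tsv")
  w(dplyr::mutate(out$clumps,
                  members = purrr::map_chr(.data$members, paste,
                                           collapse = ",")),
    "clumps.tsv")
  if (!is.null(out$scan)) w(out$scan, "scan.tsv")
  report <- out$report
  if (!is.null(out$varpart)) report$varpart <- glance.perm_null(out$varpart)
  jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(config$out_dir)
}
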