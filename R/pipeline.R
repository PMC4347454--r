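#' End-to-end imaging-genetics fusion analysis
#'
#' Chains the full procedure on in-memory inputs: genotype QC (call rate,
#' LD-based missing-call replacement, Hardy-Weinberg in controls, MAF),
#' ancestry principal-component removal, diagnosis-based SNP pre-filtering,
#' voxelwise site regression of the FA matrix, the parallel decomposition,
#' and the pairing statistics (raw + partial correlation of the top pair,
#' Bonferroni over all pairs, loading group differences, site-by-diagnosis
#' check).
#'
#' @param fa subjects-by-voxels FA [modality_matrix()].
#' @param genotypes a [genotype_table()], same subject order.
#' @param covariates data frame with columns `id`, `diagnosis`, `site`,
#'   `age`, `sex`, `ethnicity`, aligned to the FA rows.
#' @param config a [pica_config()]; when NULL the FA order is chosen by
#'   MDL and the SNP order by run-to-run consistency.
#' @param qc list of QC thresholds: `call_rate_subject`, `call_rate_snp`,
#'   `hwe_p`, `maf`, `ld_r2`, `ld_window`.
#' @param prefilter_alpha per-SNP group-difference retention threshold.
#' @param control_label value of `diagnosis` marking controls.
#' @param max_pcs_ancestry leading PCs examined for ancestry flagging.
#' @param seed master seed for every stochastic stage.
#' @return a `pica_pipeline` list with the QC reports, selected SNP
#'   indices, the decomposition `fit`, the top `pair` statistics, loading
#'   group differences and the site-by-diagnosis table.
#' @export
run_pipeline <- function(fa, genotypes, covariates, config = NULL,
                         qc = list(), prefilter_alpha = 0.01,
                         control_label = "control",
                         max_pcs_ancestry = 10L, seed = 1L) {
  qc <- utils::modifyList(list(call_rate_subject = 0.9, call_rate_snp = 0.9,
                               hwe_p = 1e-6, maf = 0.05,
                               ld_r2 = 0.8, ld_window = 50L), qc)
  assert_that(all(c("id", "diagnosis", "site") %in% names(covariates)),
              "covariates must contain id, diagnosis and site columns")
  assert_that(nrow(covariates) == nrow(fa) &&
                identical(covariates$id, rownames(fa)),
              "covariates must align with the FA matrix rows")

  reports <- list()
  s1 <- filter_call_rate(genotypes, qc$call_rate_subject, qc$call_rate_snp)
  reports$call_rate <- s1$report
  s2 <- impute_missing_by_ld(s1$table, qc$ld_r2, qc$ld_window)
  reports$ld_impute <- s2$report
  keep_subj <- match(s2$table$subjects, covariates$id)
  covariates <- covariates[keep_subj, , drop = FALSE]
  fa <- modality_matrix(mm_values(fa)[keep_subj, , drop = FALSE],
                        subjects = covariates$id, modality = "fa")
  ctrl_ids <- covariates$id[covariates$diagnosis == control_label]
  assert_that(length(ctrl_ids) >= 2, "too few controls after QC")
  s3 <- filter_hwe(s2$table, ctrl_ids, qc$hwe_p)
  reports$hwe <- s3$report
  s4 <- filter_maf(s3$table, qc$maf)
  reports$maf <- s4$report

  X2 <- genotype_to_modality(s4$table)
  anc <- ancestry_correct(X2, covariates$ethnicity, max_pcs_ancestry)
  reports$ancestry <- list(removed = anc$removed, p_values = anc$p_values)
  selected <- prefilter_group_difference(anc$matrix, covariates$diagnosis,
                                         prefilter_alpha)
  assert_that(length(selected) >= 4, "pre-filtering retained too few SNPs")
  X2f <- modality_matrix(mm_values(anc$matrix)[, selected, drop = FALSE],
                         subjects = covariates$id, modality = "snp")

  fa_corr <- regress_out_site(fa, covariates$site,
                              allow_single_site = TRUE)

  if (is.null(config)) {
    k1 <- max(2L, estimate_ncomp_mdl(fa_corr))
    k2 <- estimate_ncomp_consistency(
      X2f, candidate_ks = 2:min(10L, nrow(X2f) - 1L),
      seed = derive_seed(seed, "consistency"))$k
    config <- pica_config(n_comp_fa = k1, n_comp_snp = k2,
                          seed = derive_seed(seed, "pica"))
  }
  fit <- run_parallel_ica(fa_corr, X2f, config)
  pair <- linked_pair_stats(fit, covariates)
  fa_group <- group_difference_loadings(fit$A1[, pair$fa_component],
                                        covariates$diagnosis)
  snp_group <- group_difference_loadings(fit$A2[, pair$snp_component],
                                         covariates$diagnosis)
  site_dx <- check_site_by_diagnosis(fit$A1[, pair$fa_component],
                                     covariates$site, covariates$diagnosis)

  structure(list(reports = reports, selected_snps = selected,
                 snp_ids = s4$table$snp_info$id[selected],
                 covariates = covariates, fa = fa_corr, snp = X2f,
                 fit = fit, pair = pair,
                 fa_group_difference = fa_group,
                 snp_group_difference = snp_group,
                 site_by_diagnosis = site_dx,
                 config = config, seed = seed),
            class = "pica_pipeline")
}

#' @export
print.pica_pipeline <- function(x, ...) {
  cat(sprintf("<pica_pipeline: %d subjects, %d pre-filtered SNPs>\n",
              nrow(x$covariates), length(x$selected_snps)))
  print(x$pair)
  invisible(x)
}

#' Write an analysis report bundle
#'
#' Emits loadings and component weight tables as delimited text, the pair
#' statistics plus config echo as JSON, and a short human-readable summary.
#'
#' @param pipeline a `pica_pipeline` (or list with `fit` and `pair`).
#' @param dir output directory.
#' @param permutation optional `permutation_result`; its null sample is
#'   written as CSV.
#' @return the directory, invisibly.
#' @export
write_report <- function(pipeline, dir, permutation = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fit <- pipeline$fit
  write_modality_matrix(modality_matrix(fit$A1), file.path(dir, "loadings_fa.tsv"))
  write_modality_matrix(modality_matrix(fit$A2), file.path(dir, "loadings_snp.tsv"))
  write_modality_matrix(modality_matrix(fit$S1), file.path(dir, "components_fa.tsv"))
  write_modality_matrix(modality_matrix(fit$S2), file.path(dir, "components_snp.tsv"))
  pair <- pipeline$pair
  jsonlite::write_json(list(
    pair = pair[c("fa_component", "snp_component", "raw_r", "raw_p",
                  "partial_r", "partial_p", "m_tests", "bonferroni",
                  "passes_bonferroni", "covariates_used")],
    converged = fit$converged, iterations = fit$iterations,
    config = unclass(pipeline$config), seed = pipeline$seed),
    file.path(dir, "report.json"), auto_unbox = TRUE, digits = NA)
  if (!is.null(permutation)) {
    utils::write.csv(data.frame(null_top_corr = permutation$null),
                     file.path(dir, "permutation_null.csv"),
                     row.names = FALSE)
  }
  summary_lines <- c(
    sprintf("Top pair: FA component %d x SNP component %d",
            pair$fa_component, pair$snp_component),
    sprintf("  raw r = %.4f (p = %.3g)", pair$raw_r, pair$raw_p),
    sprintf("  partial r = %.4f (p = %.3g), covariates: %s",
            pair$partial_r, pair$partial_p,
            paste(pair$covariates_used, collapse = ", ")),
    sprintf("  Bonferroni threshold %.3g over %d tests: %s",
            pair$bonferroni, pair$m_tests,
            if (pair$passes_bonferroni) "PASS" else "fail"),
    if (!is.null(permutation))
      sprintf("  permutation p = %.3g (%d runs)", permutation$p,
              permutation$n_permutations))
  writeLines(summary_lines, file.path(dir, "summary.txt"))
  invisible(dir)
}
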