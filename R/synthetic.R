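#' Configuration of the synthetic linked-cohort generator
#'
#' Defaults emulate the study conditions the pipeline targets: 73 cases and
#' 87 controls scanned at 4 sites, a pre-filtered SNP panel of about a
#' thousand loci in Hardy-Weinberg equilibrium with MAF comfortably above
#' 0.05, nine FA and seven SNP components, and one planted linked pair
#' whose subject loadings correlate at r = -0.37 with opposite-direction
#' group mean shifts (FA loading higher in controls, SNP loading higher in
#' cases).
#'
#' @param n_cases,n_controls group sizes (sum >= 20).
#' @param n_voxels,n_snps variable counts per modality.
#' @param n_components_fa,n_components_snp true component counts.
#' @param linked_corr_target sample correlation planted between the linked
#'   loading columns (pre-noise), in \code{[-1, 1]}.
#' @param group_effect_fa,group_effect_snp group mean shifts on the linked
#'   loadings, in units of the loading's unit-variance base.
#' @param sparsity_fa,sparsity_snp fraction of variables active in the
#'   linked (and every other) component, in (0, 1).
#' @param maf_range interval the per-SNP minor allele frequency is drawn
#'   from; lower bound > 0.
#' @param n_sites number of acquisition sites.
#' @param site_effect_sd SD of the additive per-site, per-voxel FA offsets.
#' @param noise_sd_fa,noise_sd_snp additive Gaussian noise SDs.
#' @param missing_rate fraction of genotype calls set missing, in [0, 1);
#'   the default 0 reflects an analysis-ready (post-QC) panel, since the
#'   generated loci carry no linkage disequilibrium to stand in as proxies.
#' @param seed master seed; all randomness derives from it.
#' @return a `synth_config` list.
#' @export
synth_config <- function(n_cases = 73L, n_controls = 87L,
                         n_voxels = 5000L, n_snps = 1000L,
                         n_components_fa = 9L, n_components_snp = 7L,
                         linked_corr_target = -0.37,
                         group_effect_fa = 1.0, group_effect_snp = 1.2,
                         sparsity_fa = 0.05, sparsity_snp = 0.1,
                         maf_range = c(0.1, 0.45),
                         n_sites = 4L, site_effect_sd = 0.3,
                         noise_sd_fa = 0.3, noise_sd_snp = 0.5,
                         missing_rate = 0, seed = 1L) {
  assert_that(n_cases + n_controls >= 20, "need at least 20 subjects")
  assert_that(abs(linked_corr_target) <= 1,
              "linked_corr_target must lie in [-1, 1]")
  assert_that(maf_range[1] > 0 && maf_range[2] <= 0.5 &&
                maf_range[1] <= maf_range[2],
              "maf_range must be an interval inside (0, 0.5]")
  assert_that(sparsity_fa > 0 && sparsity_fa < 1 &&
                sparsity_snp > 0 && sparsity_snp < 1,
              "sparsity fractions must lie in (0, 1)")
  assert_that(missing_rate >= 0 && missing_rate < 1,
              "missing_rate must lie in [0, 1)")
  n <- n_cases + n_controls
  assert_that(n_components_fa <= min(n, n_voxels) &&
                n_components_snp <= min(n, n_snps),
              "component counts cannot exceed min(subjects, variables)")
  structure(as.list(environment())[names(formals(synth_config))],
            class = "synth_config")
}

# Sparse component matrix: each component's active variables form contiguous
# runs inside its own segment of the variable axis (components disjoint),
# active weights Gaussian, rows scaled to unit variance.
make_sparse_components <- function(k, p, sparsity) {
  S <- matrix(0, k, p)
  seg <- split(seq_len(p), cut(seq_len(p), k, labels = FALSE))
  for (r in seq_len(k)) {
    n_active <- max(3L, round(sparsity * p))
    run_len <- max(3L, min(50L, n_active))
    n_runs <- max(1L, round(n_active / run_len))
    avail <- seg[[r]]
    starts <- sample(avail[seq_len(max(1L, length(avail) - run_len))],
                     n_runs, replace = TRUE)
    idx <- unique(unlist(lapply(starts, function(s)
      s:min(s + run_len - 1L, max(avail)))))
    S[r, idx] <- rnorm(length(idx))
  }
  S / apply(S, 1L, sd)
}

# Linked loading pair with exact sample correlation `target` after the group
# mean shifts are included. Base directions are empirically orthonormalized
# against the centered group indicator, so the planted correlation is exact
# by construction, not just in expectation.
make_linked_loadings <- function(group_ctrl, target, d_fa, d_snp) {
  g <- as.numeric(group_ctrl)
  gt <- g - mean(g)
  v <- var(gt)
  z1 <- rnorm(length(g)); z2 <- rnorm(length(g))
  u1 <- std1(stats::residuals(lm(z1 ~ gt)))
  u2 <- std1(stats::residuals(lm(z2 ~ gt + u1)))
  x <- u1 + d_fa * gt
  g1 <- target * sqrt((1 + d_fa^2 * v) * (1 + d_snp^2 * v)) + d_fa * d_snp * v
  assert_that(abs(g1) <= 1,
              "linked_corr_target is infeasible given the group effects")
  y <- g1 * u1 - d_snp * gt + sqrt(1 - g1^2) * u2
  list(fa = x, snp = y)
}

#' Generate a two-modality cohort with a planted linked component pair
#'
#' Builds ground-truth loadings and sparse components for both modalities,
#' plants one (FA component, SNP component) pair whose subject loadings
#' have an exact sample correlation at the configured target plus
#' opposite-direction diagnosis mean shifts, then forms the observed data:
#' the FA matrix as signal + additive per-site voxel offsets + Gaussian
#' noise, and the genotypes by quantile-discretizing a continuous latent
#' SNP matrix so each SNP's marginal genotype frequencies follow
#' Hardy-Weinberg proportions at a MAF drawn from `maf_range`. Missing
#' calls are inserted completely at random at the configured rate.
#'
#' @param config a [synth_config()].
#' @return list with `fa` ([modality_matrix()]), `genotypes`
#'   ([genotype_table()]), `covariates` (data frame: id, diagnosis, site,
#'   age, sex, ethnicity), and `truth` (a `synthetic_truth`).
#' @export
generate_linked_dataset <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  n <- config$n_cases + config$n_controls
  k1 <- config$n_components_fa; k2 <- config$n_components_snp

  covariates <- with_seed(derive_seed(config$seed, "covariates"), {
    data.frame(
      id = sprintf("S%03d", seq_len(n)),
      diagnosis = rep(c("case", "control"),
                      c(config$n_cases, config$n_controls)),
      site = sample(sprintf("site%d", seq_len(config$n_sites)), n,
                    replace = TRUE),
      age = round(pmin(65, pmax(18, rnorm(n, 36, 11)))),
      sex = sample(c("F", "M"), n, replace = TRUE),
      ethnicity = sample(c("eur", "afr", "asia"), n, replace = TRUE,
                         prob = c(0.84, 0.10, 0.06)),
      stringsAsFactors = FALSE)
  })
  is_ctrl <- covariates$diagnosis == "control"

  linked <- c(fa = min(3L, k1), snp = min(2L, k2))
  truthA <- with_seed(derive_seed(config$seed, "loadings"), {
    A1 <- matrix(rnorm(n * k1), n, k1)
    A2 <- matrix(rnorm(n * k2), n, k2)
    lk <- make_linked_loadings(is_ctrl, config$linked_corr_target,
                               config$group_effect_fa,
                               config$group_effect_snp)
    A1[, linked["fa"]] <- lk$fa
    A2[, linked["snp"]] <- lk$snp
    list(A1 = A1, A2 = A2)
  })

  S1 <- with_seed(derive_seed(config$seed, "components-fa"),
                  make_sparse_components(k1, config$n_voxels,
                                         config$sparsity_fa))
  S2 <- with_seed(derive_seed(config$seed, "components-snp"),
                  make_sparse_components(k2, config$n_snps,
                                         config$sparsity_snp))

  site_f <- factor(covariates$site)
  site_effects <- with_seed(derive_seed(config$seed, "site-effects"),
                            matrix(rnorm(nlevels(site_f) * config$n_voxels,
                                         0, config$site_effect_sd),
                                   nlevels(site_f), config$n_voxels))
  noise1 <- with_seed(derive_seed(config$seed, "noise-fa"),
                      matrix(rnorm(n * config$n_voxels, 0,
                                   config$noise_sd_fa), n, config$n_voxels))
  X1 <- truthA$A1 %*% S1 + site_effects[as.integer(site_f), , drop = FALSE] +
    noise1

  latent2 <- truthA$A2 %*% S2 +
    with_seed(derive_seed(config$seed, "noise-snp"),
              matrix(rnorm(n * config$n_snps, 0, config$noise_sd_snp),
                     n, config$n_snps))
  gen <- with_seed(derive_seed(config$seed, "genotypes"), {
    maf <- runif(config$n_snps, config$maf_range[1], config$maf_range[2])
    calls <- matrix(0, n, config$n_snps)
    for (j in seq_len(config$n_snps)) {
      q <- maf[j]
      n2 <- round(q^2 * n)
      n0 <- round((1 - q)^2 * n)
      n0 <- min(n0, n - n2)
      rk <- rank(latent2[, j], ties.method = "first")
      calls[, j] <- ifelse(rk <= n0, 0, ifelse(rk > n - n2, 2, 1))
    }
    if (config$missing_rate > 0) {
      n_miss <- round(config$missing_rate * length(calls))
      calls[sample(length(calls), n_miss)] <- NA
    }
    list(calls = calls, maf = maf)
  })
  snp_info <- data.frame(id = sprintf("rs%06d", seq_len(config$n_snps)),
                         chr = 1L, pos = seq_len(config$n_snps) * 1000L,
                         minor = "A", major = "G", stringsAsFactors = FALSE)

  truth <- structure(list(
    true_S1 = S1, true_S2 = S2,
    true_A1 = truthA$A1, true_A2 = truthA$A2,
    linked_pair = if (config$linked_corr_target == 0 &&
                      config$group_effect_fa == 0 &&
                      config$group_effect_snp == 0) NULL else linked,
    active_fa = which(S1[linked["fa"], ] != 0),
    active_snp = which(S2[linked["snp"], ] != 0),
    site_effects = site_effects,
    drawn_maf = gen$maf,
    covariates = covariates,
    config = config), class = "synthetic_truth")

  list(fa = modality_matrix(X1, subjects = covariates$id,
                            variables = sprintf("vox%05d",
                                                seq_len(config$n_voxels)),
                            modality = "fa"),
       genotypes = genotype_table(gen$calls, snp_info = snp_info,
                                  subjects = covariates$id),
       covariates = covariates,
       truth = truth)
}

#' Generate a null cohort (no linked pair, no group effects)
#'
#' [generate_linked_dataset()] with the linked correlation target and both
#' group effects forced to zero; the ground truth marks the linked pair as
#' absent. Used for permutation-calibration and type-I-error checks.
#'
#' @param config a [synth_config()]; the overridden fields are ignored.
#' @return same structure as [generate_linked_dataset()].
#' @export
generate_null_dataset <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  config$linked_corr_target <- 0
  config$group_effect_fa <- 0
  config$group_effect_snp <- 0
  generate_linked_dataset(config)
}

#' Score recovery of the planted structure
#'
#' Greedily matches estimated components to true components per modality by
#' absolute correlation of their weight vectors (rows), reporting the
#' per-component recovery correlation and sign alignment — the matching is
#' invariant to component permutation and sign flips — plus whether the
#' decomposition's constrained top pair coincides with the planted pair.
#'
#' @param result a `pica_result`.
#' @param truth a `synthetic_truth` with the same subject ordering.
#' @return a `recovery_report` with `fa` and `snp` match tables, the
#'   `linked_recovery` correlations, and `pair_matched`.
#' @export
score_recovery <- function(result, truth) {
  assert_that(ncol(result$S1) == ncol(truth$true_S1) &&
                ncol(result$S2) == ncol(truth$true_S2),
              "variable dimensions of result and truth differ")
  match_mod <- function(S_est, S_true) {
    cm <- cor(t(S_true), t(S_est))
    gm <- greedy_match(cm)
    data.frame(true = gm$rows, est = gm$cols, corr = gm$corr,
               sign = vapply(seq_along(gm$rows), function(i)
                 sign(cm[gm$rows[i], gm$cols[i]]), numeric(1)))
  }
  fa <- match_mod(result$S1, truth$true_S1)
  snp <- match_mod(result$S2, truth$true_S2)
  pair_matched <- FALSE
  linked_recovery <- c(fa = NA_real_, snp = NA_real_)
  if (!is.null(truth$linked_pair)) {
    efa <- fa$est[fa$true == truth$linked_pair["fa"]]
    esnp <- snp$est[snp$true == truth$linked_pair["snp"]]
    linked_recovery <- c(fa = fa$corr[fa$true == truth$linked_pair["fa"]],
                         snp = snp$corr[snp$true == truth$linked_pair["snp"]])
    pair_matched <- result$constrained_pair["fa"] == efa &&
      result$constrained_pair["snp"] == esnp
  }
  structure(list(fa = fa, snp = snp, linked_recovery = linked_recovery,
                 pair_matched = pair_matched),
            class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat(sprintf(paste0("<recovery_report: median |corr| FA %.3f, SNP %.3f; ",
                     "linked pair %s>\n"),
              median(x$fa$corr), median(x$snp$corr),
              if (isTRUE(x$pair_matched)) "matched" else "not matched"))
  invisible(x)
}

#' Write a synthetic dataset to disk
#'
#' Emits the FA matrix as tab-separated text (optionally also as one NIfTI
#' volume per subject plus a mask on a synthetic 3-D grid), the genotypes
#' as both a dosage table and a PLINK bed/bim/fam trio, the covariates as
#' CSV, and the ground-truth bundle as JSON + delimited component/loading
#' tables.
#'
#' @param data output of [generate_linked_dataset()].
#' @param dir output directory.
#' @param nifti also write NIfTI volumes (default FALSE).
#' @return the directory, invisibly.
#' @export
write_synthetic_dataset <- function(data, dir, nifti = FALSE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_modality_matrix(data$fa, file.path(dir, "fa_matrix.tsv"))
  write_dosage(data$genotypes, file.path(dir, "genotypes.tsv"))
  write_plink(data$genotypes, file.path(dir, "genotypes"))
  utils::write.csv(data$covariates, file.path(dir, "covariates.csv"),
                   row.names = FALSE)
  if (nifti) write_fa_stack(mm_values(data$fa), file.path(dir, "nifti"))
  tr <- data$truth
  write_modality_matrix(modality_matrix(tr$true_A1), file.path(dir, "true_A1.tsv"))
  write_modality_matrix(modality_matrix(tr$true_A2), file.path(dir, "true_A2.tsv"))
  write_modality_matrix(modality_matrix(tr$true_S1), file.path(dir, "true_S1.tsv"))
  write_modality_matrix(modality_matrix(tr$true_S2), file.path(dir, "true_S2.tsv"))
  jsonlite::write_json(list(linked_pair = tr$linked_pair,
                            active_fa = tr$active_fa,
                            active_snp = tr$active_snp,
                            drawn_maf = tr$drawn_maf,
                            config = unclass(tr$config)),
                       file.path(dir, "truth.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}
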