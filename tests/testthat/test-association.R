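test_that("pair correlation matrix covers all component pairs", {
  set.seed(1)
  A1 <- matrix(rnorm(160 * 9), 160, 9)
  A2 <- matrix(rnorm(160 * 7), 160, 7)
  pm <- pair_correlation_matrix(A1, A2)
  expect_equal(length(pm$r), 63L)
  expect_equal(dim(pm$p), c(9L, 7L))
  A2[, 1] <- A1[, 1]
  pm2 <- pair_correlation_matrix(A1, A2)
  expect_equal(pm2$r[1, 1], 1)
  # r and p agree with the standard test on random pairs
  for (j in 1:3) {
    ct <- cor.test(A1[, j], A2[, j + 1])
    expect_equal(pm$r[j, j + 1], unname(ct$estimate), tolerance = 1e-12)
    expect_equal(pm$p[j, j + 1], ct$p.value, tolerance = 1e-10)
  }
  expect_error(pair_correlation_matrix(A1[1:3, ], A2[1:3, ]), "4 subjects")
})

test_that("partial correlation reduces correctly and matches the recursive formula", {
  set.seed(2)
  n <- 40
  cv <- rnorm(n)
  a <- 0.5 * cv + rnorm(n)
  # b equal to a covariate: nothing left after residualization
  pc0 <- partial_correlation(a, cv + 0, cbind(cv))
  expect_lt(abs(pc0$r), 1e-10)
  # no covariates: plain Pearson
  b <- rnorm(n)
  expect_equal(partial_correlation(a, b)$r, cor(a, b), tolerance = 1e-12)
  expect_equal(partial_correlation(a, b)$p, cor.test(a, b)$p.value,
               tolerance = 1e-10)
  # 8-point example against the recursive partial-correlation identity
  a8 <- c(1.2, -0.4, 0.8, 2.1, -1.5, 0.3, 1.9, -0.2)
  b8 <- c(0.5, 1.1, -0.9, 1.4, -0.8, 0.2, 2.2, -1.0)
  c8 <- c(0.1, 0.7, -0.3, 1.0, -1.2, 0.5, 1.1, -0.6)
  r_ab <- cor(a8, b8); r_ac <- cor(a8, c8); r_bc <- cor(b8, c8)
  oracle <- (r_ab - r_ac * r_bc) / sqrt((1 - r_ac^2) * (1 - r_bc^2))
  expect_equal(partial_correlation(a8, b8, cbind(c8))$r, oracle,
               tolerance = 1e-12)
  # invariance to affine covariate rescaling
  d8 <- c(2.0, -1.1, 0.4, 0.9, 1.3, -0.7, 0.6, -1.8)
  p1 <- partial_correlation(a8, b8, cbind(c8, d8))
  p2 <- partial_correlation(a8, b8, cbind(10 * c8 - 3, -0.2 * d8 + 7))
  expect_equal(p1$r, p2$r, tolerance = 1e-10)
  expect_equal(p1$p, p2$p, tolerance = 1e-10)
  expect_error(partial_correlation(a8, b8, cbind(c8, 2 * c8)),
               "rank deficient")
})

test_that("Bonferroni threshold is exact", {
  expect_equal(bonferroni_threshold(0.05, 63) * 63, 0.05)
  expect_equal(bonferroni_threshold(0.05, 1), 0.05)
  expect_equal(bonferroni_threshold(0.01, 10), 0.001)
})

test_that("loading group difference matches the textbook computation", {
  dx <- rep(c("case", "control"), each = 5)
  ld <- c(1.2, 0.8, 1.5, 1.1, 0.9, 0.4, 0.2, 0.7, 0.3, 0.5)
  out <- group_difference_loadings(ld, dx, var_equal = TRUE)
  m1 <- mean(ld[1:5]); m2 <- mean(ld[6:10])
  sp <- sqrt((4 * var(ld[1:5]) + 4 * var(ld[6:10])) / 8)
  t_hand <- (m1 - m2) / (sp * sqrt(2 / 5))
  expect_equal(out$t, t_hand, tolerance = 1e-12)
  expect_equal(out$p, 2 * pt(-abs(t_hand), 8), tolerance = 1e-12)
  # identical group distributions: t = 0, p = 1
  same <- rep(c(1, 2, 3, 4, 5), 2)
  expect_equal(group_difference_loadings(same, dx)$p, 1)
})

test_that("group-difference power matches the noncentral-t oracle", {
  n1 <- 73; n2 <- 87; d <- 1
  ncp <- d / sqrt(1 / n1 + 1 / n2)
  crit <- qt(1 - 5e-7, df = n1 + n2 - 2)           # two-sided 1e-6
  power_oracle <- pt(crit, df = n1 + n2 - 2, ncp = ncp, lower.tail = FALSE)
  set.seed(3)
  hits <- mean(replicate(300, {
    ld <- c(rnorm(n1, d), rnorm(n2, 0))
    group_difference_loadings(ld, rep(c("a", "b"), c(n1, n2)))$p < 1e-6
  }))
  expect_lt(abs(hits - power_oracle), 3 * sqrt(power_oracle *
                                                 (1 - power_oracle) / 300) + 0.02)
})

test_that("within-group correlation separates group-mean-driven links", {
  set.seed(4)
  n <- 160
  g <- rep(c(TRUE, FALSE), c(73, 87))
  a <- as.numeric(g) + rnorm(n, 0, 0.5)
  b <- -as.numeric(g) + rnorm(n, 0, 0.5)
  pooled <- partial_correlation(a, b)
  expect_lt(pooled$r, -0.4)
  w1 <- within_group_partial_correlation(a, b, NULL, g)
  w2 <- within_group_partial_correlation(a, b, NULL, !g)
  expect_lt(abs(w1$r), 0.25)
  expect_lt(abs(w2$r), 0.25)
  # full-cohort mask reduces to the plain partial correlation
  wall <- within_group_partial_correlation(a, b, NULL, rep(TRUE, n))
  expect_equal(wall$r, pooled$r)
  expect_error(within_group_partial_correlation(a, b, cbind(rnorm(n)),
                                                c(rep(TRUE, 4), rep(FALSE, n - 4))),
               "too few")
})

test_that("empirical p is the exact counting rule", {
  null <- c(0.1, 0.2, 0.3, 0.4)
  expect_equal(empirical_p(0.25, null), 0.5)
  expect_equal(empirical_p(0.05, null), 1)       # below the null minimum
  expect_equal(empirical_p(0.5, null), 0)
  # adding null values below the observed never changes the numerator
  expect_equal(empirical_p(0.25, c(null, 0.01, 0.02)) * 6,
               empirical_p(0.25, null) * 4)
})

test_that("permutation test honors its contract on a small run", {
  d <- generate_null_dataset(small_config(seed = 31))
  X2 <- genotype_to_modality(d$genotypes)
  pr <- permutation_test(d$fa, X2, reduced_profile(seed = 2), n_perm = 25,
                         perm_config = reduced_profile(seed = 2), seed = 7)
  expect_length(pr$null, 25L)
  expect_equal(pr$p, sum(pr$null >= pr$observed) / 25)
  expect_true(all(pr$null >= 0 & pr$null <= 1))
  # precomputed observed skips the observed decomposition
  pr2 <- permutation_test(d$fa, X2, reduced_profile(seed = 2), n_perm = 10,
                          seed = 7, observed = 0)
  expect_equal(pr2$p, 1)
})

test_that("overlap ratio counts against the full-data set", {
  expect_equal(overlap_ratio(1:326, 1:326), 1)
  expect_equal(overlap_ratio(400:500, 1:100), 0)
  expect_equal(overlap_ratio(c(1:200, 400:525), 1:326), 200 / 326)
  expect_error(overlap_ratio(1:5, integer(0)), "nonempty")
})

test_that("k-fold reproduces the linked pair on synthetic data", {
  cfg <- synth_config(n_voxels = 800, n_snps = 300, seed = 51)
  d <- generate_linked_dataset(cfg)
  X2 <- genotype_to_modality(d$genotypes)
  kf <- kfold_reproducibility(d$fa, X2, pica_config(9, 7, seed = 5,
                                                    max_iterations = 200),
                              k = 10, diagnosis = d$covariates$diagnosis,
                              seed = 4)
  fc <- vapply(kf$folds, `[[`, numeric(1), "pair_corr")
  n_used <- vapply(kf$folds, `[[`, numeric(1), "n_used")
  expect_true(all(n_used >= floor(0.9 * 160) - 1))
  expect_lt(abs(median(abs(fc)) - abs(kf$full$constrained_corr)), 0.15)
  ov <- vapply(kf$folds, `[[`, numeric(1), "overlap")
  expect_gt(median(ov), 0.5)
})

test_that("leave-one-out folds run on tiny data", {
  d <- generate_linked_dataset(synth_config(n_cases = 10, n_controls = 10,
                                            n_voxels = 60, n_snps = 40,
                                            n_components_fa = 2,
                                            n_components_snp = 2, seed = 3))
  X2 <- genotype_to_modality(d$genotypes)
  kf <- kfold_reproducibility(d$fa, X2,
                              pica_config(2, 2, max_iterations = 10, seed = 1),
                              k = 20, diagnosis = d$covariates$diagnosis,
                              seed = 2)
  expect_length(kf$folds, 20L)
})

test_that("subgroup rerun matches the full run for an all-true mask", {
  d <- generate_linked_dataset(small_config(seed = 61))
  X2 <- genotype_to_modality(d$genotypes)
  cfg <- pica_config(3, 3, max_iterations = 60, seed = 9)
  full <- run_parallel_ica(d$fa, X2, cfg)
  sg <- subgroup_rerun(d$fa, X2, d$covariates, rep(TRUE, nrow(d$fa)), cfg)
  expect_equal(sg$fit$constrained_corr, full$constrained_corr,
               tolerance = 1e-12)
  expect_error(subgroup_rerun(d$fa, X2, d$covariates,
                              d$covariates$diagnosis == "case", cfg),
               "both diagnostic groups")
})

test_that("a link survives in a subgroup that preserves it", {
  d <- generate_linked_dataset(synth_config(n_voxels = 800, n_snps = 300,
                                            seed = 62))
  X2 <- genotype_to_modality(d$genotypes)
  mask <- d$covariates$ethnicity == "eur"   # ~84% of subjects
  sg <- subgroup_rerun(d$fa, X2, d$covariates, mask,
                       pica_config(9, 7, max_iterations = 200, seed = 11))
  expect_gt(abs(sg$pair$raw_r), 0.2)
  expect_true(sg$pair$raw_p < 0.05)
})

test_that("raw p-values pass Bonferroni rarely under the null generator", {
  # the constraint biases the top pair's raw p; this smoke test bounds the
  # anti-conservativity, which is why the permutation test is authoritative
  passes <- vapply(1:50, function(s) {
    d <- generate_null_dataset(synth_config(n_voxels = 400, n_snps = 300,
                                            seed = s))
    X2 <- genotype_to_modality(d$genotypes)
    fit <- run_parallel_ica(d$fa, X2,
                            pica_config(9, 7, max_iterations = 60,
                                        seed = s + 500))
    pm <- pair_correlation_matrix(fit$A1, fit$A2)
    min(pm$p) < bonferroni_threshold(0.05, 63)
  }, logical(1))
  expect_lte(mean(passes), 0.10)
})
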