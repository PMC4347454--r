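test_that("call-rate filter removes SNPs and subjects by hand-counted rates", {
  # SNP 3 missing in 2 of 10 subjects: call rate 0.8 -> removed; the
  # relaxed subject threshold isolates the SNP-level filter
  calls <- matrix(1, 10, 5)
  calls[1:2, 3] <- NA
  res <- filter_call_rate(genotype_table(calls), subject_min = 0.7)
  expect_equal(ncol(res$table$calls), 4L)
  expect_equal(res$report$n_snps_removed, 1L)
  expect_equal(res$report$n_subjects_removed, 0L)

  calls <- matrix(0, 10, 5)
  calls[1, 1:3] <- NA          # subject 1 call rate 0.4 -> removed
  res2 <- filter_call_rate(genotype_table(calls))
  expect_equal(res2$report$n_subjects_removed, 1L)
  expect_false("S001" %in% res2$table$subjects)

  clean <- genotype_table(matrix(1, 6, 4))
  res3 <- filter_call_rate(clean)
  expect_identical(res3$table$calls, clean$calls)
})

test_that("subject filtering happens before SNP filtering", {
  # SNP 1 is missing only in subject 1; subject 1 also misses 3 of 5 SNPs.
  # Once subject 1 is dropped, SNP 1 is complete and must be retained.
  calls <- matrix(2, 10, 5)
  calls[1, c(1, 2, 3)] <- NA
  res <- filter_call_rate(genotype_table(calls))
  expect_equal(res$report$n_subjects_removed, 1L)
  expect_equal(res$report$n_snps_removed, 0L)
})

test_that("exact HWE test matches closed cases and the enumeration oracle", {
  expect_equal(hwe_test(25, 50, 25), 1, tolerance = 1e-9)
  expect_lt(hwe_test(0, 100, 0), 1e-6)
  set.seed(21)
  for (i in 1:200) {
    n <- sample(5:150, 1)
    nAa <- sample(0:n, 1)
    nAA <- sample(0:(n - nAa), 1)
    naa <- n - nAa - nAA
    expect_equal(hwe_test(nAA, nAa, naa), hwe_oracle(nAA, nAa, naa),
                 tolerance = 1e-10)
  }
  expect_error(hwe_test(0, 0, 0), "at least one")
})

test_that("HWE filter uses controls only", {
  set.seed(17)
  calls <- matrix(rbinom(80 * 6, 2, 0.4), 80, 6)
  gt <- genotype_table(calls)
  controls <- gt$subjects[1:40]
  # SNP 6: extreme heterozygote excess in 40 controls -> p < 1e-6, removed
  gt$calls[1:40, 6] <- 1
  gt$calls[41:80, 6] <- rep(c(0, 2), 20)
  expect_lt(hwe_test(0, 40, 0), 1e-6)
  res <- filter_hwe(gt, controls)
  expect_false("rs000006" %in% res$table$snp_info$id)
  # SNP 5: the same violation confined to cases -> retained
  gt2 <- genotype_table(calls)
  gt2$calls[41:80, 5] <- 1
  gt2$calls[1:40, 5] <- rbinom(40, 2, 0.5)
  res2 <- filter_hwe(gt2, controls)
  expect_true("rs000005" %in% res2$table$snp_info$id)
  # perfect-HWE table unchanged
  perfect <- genotype_table(matrix(rep(rep(c(0, 1, 2), c(9, 12, 4)), 4),
                                   25, 4))
  expect_equal(ncol(filter_hwe(perfect, perfect$subjects)$table$calls), 4L)
})

test_that("MAF filter is strict at the boundary and recomputed after subject removal", {
  # 16 minor alleles across 160 subjects: MAF exactly 0.05 -> removed
  calls <- cbind(c(rep(1, 16), rep(0, 144)),
                 rbinom(160, 2, 0.3))
  res <- filter_maf(genotype_table(calls))
  expect_equal(ncol(res$table$calls), 1L)
  expect_equal(res$report$n_snps_removed, 1L)
  # all-0.5 MAF unchanged
  res2 <- filter_maf(genotype_table(matrix(1, 20, 3)))
  expect_equal(ncol(res2$table$calls), 3L)
  # order matters: SNP passes MAF only after low-call-rate subjects leave
  calls3 <- cbind(c(rep(NA, 30), rep(1, 10), rep(0, 10)), matrix(1, 50, 4))
  gt3 <- genotype_table(calls3)
  cr <- filter_call_rate(gt3, subject_min = 0.85)
  expect_equal(nrow(cr$table$calls), 20L)
  maf_after <- genotype_maf(cr$table)[1]
  expect_gt(maf_after, 0.05)
})

test_that("LD replacement fills from the best proxy with allele alignment", {
  set.seed(3)
  base <- rbinom(30, 2, 0.4)
  calls <- cbind(base, base, 2 - base, rbinom(30, 2, 0.4))
  calls[5, 1] <- NA
  gt <- genotype_table(calls)
  res <- impute_missing_by_ld(gt, r2_min = 0.9, window = 5)
  expect_equal(res$table$calls[5, 1], base[5])       # perfect positive proxy
  calls2 <- cbind(base, 2 - base, rbinom(30, 2, 0.4))
  calls2[7, 2] <- NA
  res2 <- impute_missing_by_ld(genotype_table(calls2), 0.9, 5)
  expect_equal(res2$table$calls[7, 2], 2 - base[7])  # negative proxy: 2 - g
  # isolated SNP with no proxy above r2_min is dropped
  calls3 <- cbind(base, sample(rbinom(30, 2, 0.4)))
  calls3[9, 2] <- NA
  res3 <- impute_missing_by_ld(genotype_table(calls3), 0.99, 5)
  expect_equal(ncol(res3$table$calls), 1L)
  expect_false(anyNA(res3$table$calls))
})

test_that("QC filters are idempotent", {
  set.seed(14)
  d <- generate_linked_dataset(small_config(seed = 14, missing_rate = 0.03))
  gt <- d$genotypes
  ctrl <- gt$subjects[d$covariates$diagnosis == "control"]
  f1 <- filter_call_rate(gt)
  expect_identical(filter_call_rate(f1$table)$table$calls, f1$table$calls)
  f2 <- filter_maf(f1$table)
  expect_identical(filter_maf(f2$table)$table$calls, f2$table$calls)
  ctrl2 <- intersect(ctrl, f2$table$subjects)
  f3 <- filter_hwe(f2$table, ctrl2)
  expect_identical(filter_hwe(f3$table, ctrl2)$table$calls, f3$table$calls)
})

test_that("ancestry correction flags and removes stratification components", {
  set.seed(5)
  n <- 80; p <- 400
  eth <- rep(c("pop1", "pop2"), each = n / 2)
  f1 <- runif(p, 0.1, 0.4)
  f2 <- pmin(0.5, f1 + ifelse(runif(p) < 0.5, 0.25, 0))  # shifted freqs
  calls <- t(vapply(seq_len(n), function(i) {
    fr <- if (eth[i] == "pop1") f1 else f2
    rbinom(p, 2, fr)
  }, numeric(p)))
  X <- modality_matrix(scale(calls, scale = FALSE), modality = "snp")
  res <- ancestry_correct(X, eth, max_pcs = 10)
  expect_true(1 %in% res$removed)
  # post-correction: PC1 of corrected data no longer separates populations
  sv <- svd(unclass(res$matrix), nu = 1)
  p_after <- summary(aov(sv$u[, 1] * sv$d[1] ~ factor(eth)))[[1]][["Pr(>F)"]][1]
  expect_gt(p_after, 0.05 / 10)
  # removed directions carry no remaining variance
  sv0 <- svd(unclass(X), nu = 2, nv = 2)
  for (f in res$removed) {
    expect_lt(max(abs(unclass(res$matrix) %*% sv0$v[, f])), 1e-6 * sv0$d[1])
  }
  expect_equal(dim(res$matrix), dim(X))
})

test_that("ancestry correction is a no-op for a homogeneous population", {
  set.seed(6)
  X <- modality_matrix(scale(matrix(rbinom(50 * 100, 2, 0.3), 50, 100),
                             scale = FALSE), modality = "snp")
  res <- ancestry_correct(X, rep("pop1", 50))
  expect_length(res$removed, 0)
  expect_equal(unclass(res$matrix), unclass(X), ignore_attr = TRUE)
})

test_that("diagnosis pre-filter is calibrated on independent null SNPs", {
  set.seed(31)
  n <- 160
  dx <- rep(c("case", "control"), c(73, 87))
  # independent null loci: HWE multisets assigned by latent ranks
  calls <- vapply(1:10000, function(j) {
    q <- runif(1, 0.1, 0.45)
    n2 <- round(q^2 * n); n0 <- min(round((1 - q)^2 * n), n - n2)
    rk <- rank(rnorm(n), ties.method = "first")
    ifelse(rk <= n0, 0, ifelse(rk > n - n2, 2, 1))
  }, numeric(n))
  sel <- prefilter_group_difference(modality_matrix(calls), dx, 0.01)
  expect_gt(length(sel), qbinom(0.005, 10000, 0.01))
  expect_lt(length(sel), qbinom(0.995, 10000, 0.01))
  # a strong planted shift is always selected
  calls[dx == "case", 1] <- calls[dx == "case", 1] + 0.8
  sel2 <- prefilter_group_difference(modality_matrix(calls), dx, 0.01)
  expect_true(1 %in% sel2)
  # alpha = 1 selects everything
  expect_length(prefilter_group_difference(modality_matrix(calls), dx, 1),
                10000L)
})

test_that("plink and dosage writers round-trip including missing calls", {
  set.seed(9)
  calls <- matrix(sample(c(0, 1, 2, NA), 35 * 7, replace = TRUE,
                         prob = c(0.5, 0.25, 0.15, 0.1)), 35, 7)
  calls[, 1] <- 0  # keep one monomorphic column to exercise edge handling
  gt <- genotype_table(calls)
  td <- withr::local_tempdir()
  write_plink(gt, file.path(td, "t"))
  back <- read_plink(file.path(td, "t"))
  # the reader normalizes to minor-allele counts: columns whose coded
  # allele frequency exceeds 0.5 come back flipped with swapped labels
  freq <- colMeans(calls, na.rm = TRUE) / 2
  expected <- calls
  expected[, freq > 0.5] <- 2 - expected[, freq > 0.5]
  expect_identical(unname(back$calls), unname(expected))
  expect_true(all(ifelse(freq > 0.5, back$snp_info$minor == "G",
                         back$snp_info$minor == "A")))
  write_dosage(gt, file.path(td, "t.tsv"))
  back2 <- read_dosage(file.path(td, "t.tsv"))
  expect_identical(unname(back2$calls), unname(gt$calls))
})
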