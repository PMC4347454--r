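qc_report <- function(step, n_subjects_removed = 0L, n_snps_removed = 0L,
                      ...) {
  structure(list(step = step,
                 n_subjects_removed = n_subjects_removed,
                 n_snps_removed = n_snps_removed, ...),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("<qc_report '%s': removed %d subjects, %d SNPs>\n",
              x$step, x$n_subjects_removed, x$n_snps_removed))
  invisible(x)
}

#' Call-rate filtering
#'
#' Removes subjects and then SNPs whose genotyping call rate does not
#' strictly exceed the respective threshold (default 0.9 at both levels).
#' The subject filter is applied first, so SNP call rates are computed over
#' the retained subjects.
#'
#' @param gt a [genotype_table()].
#' @param subject_min,snp_min call-rate thresholds in (0, 1].
#' @return list with the filtered `table` and a `report`.
#' @export
filter_call_rate <- function(gt, subject_min = 0.9, snp_min = 0.9) {
  assert_that(subject_min > 0 && subject_min <= 1 &&
                snp_min > 0 && snp_min <= 1, "thresholds must lie in (0, 1]")
  subj_cr <- rowMeans(!is.na(gt$calls))
  keep_s <- subj_cr > subject_min
  gt2 <- gt_subset(gt, subjects = which(keep_s))
  snp_cr <- colMeans(!is.na(gt2$calls))
  keep_v <- snp_cr > snp_min
  assert_that(any(keep_s) && any(keep_v),
              "call-rate filtering removed every subject or SNP")
  out <- gt_subset(gt2, snps = which(keep_v))
  list(table = out,
       report = qc_report("call_rate",
                          n_subjects_removed = sum(!keep_s),
                          n_snps_removed = sum(!keep_v),
                          subject_call_rate = subj_cr,
                          snp_call_rate = snp_cr))
}

#' Exact test of Hardy-Weinberg equilibrium
#'
#' Two-sided exact HWE p-value for one biallelic SNP: the distribution of
#' the heterozygote count conditional on the observed allele counts is
#' enumerated, and the p-value is the total probability of all heterozygote
#' configurations no more probable than the observed one.
#'
#' @param n_AA,n_Aa,n_aa genotype counts (major hom, het, minor hom).
#' @return the exact p-value in (0, 1].
#' @export
hwe_test <- function(n_AA, n_Aa, n_aa) {
  assert_that(n_AA >= 0 && n_Aa >= 0 && n_aa >= 0, "counts must be nonnegative")
  n <- n_AA + n_Aa + n_aa
  assert_that(n >= 1, "at least one genotyped subject required")
  rare <- min(2 * n_AA + n_Aa, 2 * n_aa + n_Aa)
  hs <- seq.int(rare %% 2L, min(rare, 2L * n - rare), by = 2L)
  # log P(het = h | n, rare) up to the shared normalizing constant
  lp <- -lfactorial((rare - hs) / 2) - lfactorial(hs) -
    lfactorial(n - (rare + hs) / 2) + hs * log(2)
  pr <- exp(lp - max(lp))
  pr <- pr / sum(pr)
  obs <- pr[match(n_Aa, hs)]
  min(1, sum(pr[pr <= obs * (1 + 1e-9)]))
}

#' Hardy-Weinberg filtering in controls
#'
#' Applies [hwe_test()] to each SNP using control subjects only (cases may
#' legitimately deviate under association) and removes SNPs with exact
#' p-value below `p_min` (default 1e-6).
#'
#' @param gt a [genotype_table()].
#' @param control_ids subject IDs of the control group.
#' @param p_min exclusion threshold on the exact p-value.
#' @return list with the filtered `table` and a `report` carrying the
#'   per-SNP p-values.
#' @export
filter_hwe <- function(gt, control_ids, p_min = 1e-6) {
  ctrl <- match(control_ids, gt$subjects)
  assert_that(!anyNA(ctrl), "unknown control subject ID")
  calls <- gt$calls[ctrl, , drop = FALSE]
  pv <- apply(calls, 2L, function(g) {
    g <- g[!is.na(g)]
    if (!length(g)) return(1)
    hwe_test(sum(g == 0), sum(g == 1), sum(g == 2))
  })
  keep <- pv >= p_min
  assert_that(any(keep), "HWE filtering removed every SNP")
  list(table = gt_subset(gt, snps = which(keep)),
       report = qc_report("hwe", n_snps_removed = sum(!keep), hwe_p = pv))
}

#' Minor-allele-frequency filtering
#'
#' Removes SNPs whose minor allele frequency (over non-missing calls, after
#' any subject removal) does not strictly exceed `maf_min` (default 0.05).
#'
#' @param gt a [genotype_table()].
#' @param maf_min strict MAF threshold.
#' @return list with the filtered `table` and a `report` carrying the MAFs.
#' @export
filter_maf <- function(gt, maf_min = 0.05) {
  maf <- genotype_maf(gt)
  keep <- maf > maf_min
  assert_that(any(keep), "MAF filtering removed every SNP")
  list(table = gt_subset(gt, snps = which(keep)),
       report = qc_report("maf", n_snps_removed = sum(!keep), maf = maf))
}

#' Replace missing calls using high-LD proxy SNPs
#'
#' Each missing call at SNP `j` is replaced by the same subject's genotype
#' at the SNP within `window` positions whose squared dosage correlation
#' with `j` is highest and at least `r2_min`; a negative dosage correlation
#' maps the proxy genotype `g` to `2 - g` (allele alignment). SNPs with a
#' missing call for which no qualifying proxy has an observed genotype are
#' removed, so the output contains no missing values. Proxy genotypes are
#' always taken from the original (pre-replacement) calls.
#'
#' @param gt a [genotype_table()].
#' @param r2_min minimum squared correlation for a usable proxy.
#' @param window number of neighboring SNPs searched on each side.
#' @return list with the completed `table` and a `report`.
#' @export
impute_missing_by_ld <- function(gt, r2_min = 0.8, window = 50L) {
  calls <- gt$calls
  p <- ncol(calls)
  out <- calls
  drop <- logical(p)
  filled <- 0L
  need <- which(colSums(is.na(calls)) > 0L)
  for (j in need) {
    cand <- setdiff(max(1L, j - window):min(p, j + window), j)
    r <- suppressWarnings(vapply(cand, function(k) {
      cc <- stats::cor(calls[, j], calls[, k], use = "pairwise.complete.obs")
      if (is.finite(cc)) cc else 0
    }, numeric(1)))
    ord <- cand[order(-r^2)]
    rs <- r[order(-r^2)]
    miss <- which(is.na(calls[, j]))
    for (s in miss) {
      done <- FALSE
      for (i in seq_along(ord)) {
        if (rs[i]^2 < r2_min) break
        g <- calls[s, ord[i]]
        if (!is.na(g)) {
          out[s, j] <- if (rs[i] > 0) g else 2 - g
          filled <- filled + 1L
          done <- TRUE
          break
        }
      }
      if (!done) { drop[j] <- TRUE; break }
    }
  }
  keep <- which(!drop)
  assert_that(length(keep) > 0, "LD replacement removed every SNP")
  list(table = gt_subset(genotype_table(out, gt$snp_info, gt$subjects),
                         snps = keep),
       report = qc_report("ld_impute", n_snps_removed = sum(drop),
                          n_calls_filled = filled))
}

#' Remove ancestry-related principal components
#'
#' Computes subject-space principal components of the centered dosage
#' matrix and flags a component as ancestry-related when a one-way ANOVA of
#' its subject scores across self-reported ethnicity labels is significant
#' (Bonferroni-corrected over the `max_pcs` components examined, family
#' alpha 0.05). Flagged component subspaces are projected out; subject and
#' SNP counts are unchanged.
#'
#' @param X2 centered subjects-by-SNPs dosage matrix ([modality_matrix()]).
#' @param ethnicity per-subject labels aligned to the rows.
#' @param max_pcs number of leading components examined (default 10).
#' @param alpha family-wise flagging level before Bonferroni division.
#' @return list with the corrected `matrix`, the `removed` PC indices, and
#'   the per-PC ANOVA `p_values`.
#' @export
ancestry_correct <- function(X2, ethnicity, max_pcs = 10L, alpha = 0.05) {
  X <- mm_values(as.matrix(X2))
  n <- nrow(X)
  assert_that(n >= 3, "at least 3 subjects required")
  assert_that(length(ethnicity) == n, "one ethnicity label per subject")
  eth <- factor(ethnicity)
  max_pcs <- min(max_pcs, n - 1L)
  sv <- svd(X, nu = max_pcs, nv = max_pcs)
  scores <- sv$u %*% diag(sv$d[seq_len(max_pcs)], max_pcs)
  if (nlevels(eth) < 2L) {
    return(list(matrix = X2, removed = integer(0),
                p_values = rep(NA_real_, max_pcs)))
  }
  pv <- vapply(seq_len(max_pcs), function(f) {
    summary(aov(scores[, f] ~ eth))[[1]][["Pr(>F)"]][1]
  }, numeric(1))
  removed <- which(pv < alpha / max_pcs)
  Xc <- X
  for (f in removed) {
    Xc <- Xc - sv$u[, f, drop = FALSE] %*%
      (sv$d[f] * t(sv$v[, f, drop = FALSE]))
  }
  out <- modality_matrix(Xc, subjects = rownames(X2),
                         variables = colnames(X2),
                         modality = attr(X2, "modality"))
  list(matrix = out, removed = removed, p_values = pv)
}

#' Diagnosis-based SNP pre-filtering
#'
#' Per-SNP two-sample test of additive dosage between diagnostic groups;
#' SNPs with p below `alpha` (default 0.01, uncorrected) are retained in
#' genomic order. This focuses the joint decomposition on loci plausibly
#' related to case status and keeps the subject-to-variable ratio workable.
#'
#' @param X2 subjects-by-SNPs dosage matrix (QC'd, ancestry-corrected).
#' @param diagnosis two-level factor/vector aligned to rows.
#' @param alpha retention threshold on the per-SNP p-value.
#' @param method `"welch"` (default) for the Welch t-test on dosage, or
#'   `"trend"` for the chi-square trend-test equivalent (pooled-variance
#'   score test).
#' @return integer indices of the selected SNPs, ascending.
#' @export
prefilter_group_difference <- function(X2, diagnosis, alpha = 0.01,
                                       method = c("welch", "trend")) {
  method <- match.arg(method)
  X <- mm_values(as.matrix(X2))
  g <- factor(diagnosis)
  assert_that(nlevels(g) == 2L, "diagnosis must have exactly two levels")
  i1 <- which(g == levels(g)[1L]); i2 <- which(g == levels(g)[2L])
  n1 <- length(i1); n2 <- length(i2)
  assert_that(n1 >= 2 && n2 >= 2, "each group needs at least 2 subjects")
  m1 <- colMeans(X[i1, , drop = FALSE]); m2 <- colMeans(X[i2, , drop = FALSE])
  v1 <- apply(X[i1, , drop = FALSE], 2L, var)
  v2 <- apply(X[i2, , drop = FALSE], 2L, var)
  if (method == "welch") {
    se2 <- v1 / n1 + v2 / n2
    tt <- (m1 - m2) / sqrt(se2)
    df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
    pv <- 2 * pt(-abs(tt), df)
  } else {
    vp <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    z <- (m1 - m2) / sqrt(vp * (1 / n1 + 1 / n2))
    pv <- pchisq(z^2, df = 1, lower.tail = FALSE)
  }
  pv[!is.finite(pv)] <- 1  # constant SNPs carry no group signal
  which(pv < alpha)
}
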