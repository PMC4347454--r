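#' Pairwise loading correlation matrix
#'
#' Pearson correlation and two-sided p-value for every (FA component, SNP
#' component) loading pair — with 9 FA and 7 SNP components this is the
#' 63-test family over which Bonferroni correction is taken.
#'
#' @param A1 subjects-by-k1 FA loading matrix.
#' @param A2 subjects-by-k2 SNP loading matrix, same subject order.
#' @return list of `r` and `p` matrices (k1 x k2).
#' @export
pair_correlation_matrix <- function(A1, A2) {
  A1 <- as.matrix(A1); A2 <- as.matrix(A2)
  n <- nrow(A1)
  assert_that(nrow(A2) == n, "loading matrices must share subjects")
  assert_that(n >= 4, "at least 4 subjects required")
  r <- cor(A1, A2)
  tt <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * pt(-abs(tt), df = n - 2)
  p[abs(r) >= 1] <- 0
  list(r = r, p = p)
}

#' Partial correlation controlling for covariates
#'
#' Residualizes both vectors on an intercept plus the covariate design by
#' ordinary least squares and correlates the residuals; the p-value uses a
#' t reference with `n - 2 - q` degrees of freedom, `q` the number of
#' covariate columns.
#'
#' @param a,b numeric vectors.
#' @param covariate_design numeric matrix (n x q) or NULL for a plain
#'   Pearson correlation.
#' @return list with `r`, `p`, `df`.
#' @export
partial_correlation <- function(a, b, covariate_design = NULL) {
  n <- length(a)
  assert_that(length(b) == n, "vectors must have equal length")
  if (is.null(covariate_design) || NCOL(covariate_design) == 0) {
    Dm <- matrix(1, n, 1)
    q <- 0L
  } else {
    Dm <- cbind(1, as.matrix(covariate_design))
    q <- ncol(Dm) - 1L
    assert_that(qr(Dm)$rank == ncol(Dm), "covariate design is rank deficient")
  }
  assert_that(n >= q + 4, "too few observations for the covariate count")
  qd <- qr(Dm)
  ra <- qr.resid(qd, a); rb <- qr.resid(qd, b)
  # a variable fully explained by the covariates has nothing left to
  # correlate: define the partial correlation as 0
  if (sd(ra) <= 1e-12 * max(sd(a), 1) || sd(rb) <= 1e-12 * max(sd(b), 1)) {
    return(list(r = 0, p = 1, df = n - 2L - q))
  }
  r <- cor(ra, rb)
  df <- n - 2L - q
  tt <- r * sqrt(df / pmax(1 - r^2, .Machine$double.eps))
  list(r = r, p = min(1, 2 * pt(-abs(tt), df = df)), df = df)
}

#' Bonferroni significance threshold
#'
#' @param alpha family-wise error rate (default 0.05).
#' @param m number of tests.
#' @return `alpha / m`; e.g. 63 loading-pair tests at alpha 0.05 give
#'   7.94e-4.
#' @export
bonferroni_threshold <- function(alpha = 0.05, m) {
  assert_that(m >= 1, "m must be >= 1")
  alpha / m
}

#' Group difference of component loadings
#'
#' Two-sample t-test (Welch by default) of a loading column between
#' diagnostic groups, with per-group means.
#'
#' @param loadings numeric loading vector.
#' @param diagnosis two-level factor/vector.
#' @param var_equal pass TRUE for the pooled-variance test.
#' @return list with `t`, `p`, `means`, `df`.
#' @export
group_difference_loadings <- function(loadings, diagnosis, var_equal = FALSE) {
  dx <- factor(diagnosis)
  assert_that(nlevels(dx) == 2L, "diagnosis must have two levels")
  tt <- t.test(loadings ~ dx, var.equal = var_equal)
  list(t = unname(tt$statistic), p = tt$p.value,
       means = tapply(loadings, dx, mean), df = unname(tt$parameter))
}

#' Within-group partial correlation
#'
#' [partial_correlation()] restricted to the subjects of one group — used
#' to ask whether a pooled-cohort loading correlation survives inside each
#' diagnostic group or is carried by the group-mean difference.
#'
#' @param a,b numeric vectors over the full cohort.
#' @param covariate_design full-cohort covariate matrix or NULL.
#' @param group_mask logical vector selecting the group.
#' @return list with `r`, `p`, `df`, `n`.
#' @export
within_group_partial_correlation <- function(a, b, covariate_design = NULL,
                                             group_mask) {
  assert_that(is.logical(group_mask) && length(group_mask) == length(a),
              "group_mask must be a logical vector over subjects")
  idx <- which(group_mask)
  cd <- if (is.null(covariate_design)) NULL else
    as.matrix(covariate_design)[idx, , drop = FALSE]
  if (!is.null(cd)) {
    # drop covariate columns that become constant inside the group
    keep <- apply(cd, 2L, function(x) var(x) > 0)
    cd <- cd[, keep, drop = FALSE]
    if (ncol(cd) == 0) cd <- NULL
  }
  out <- partial_correlation(a[idx], b[idx], cd)
  out$n <- length(idx)
  out
}

#' Empirical tail probability from a permutation null
#'
#' `p = #{null >= observed} / length(null)` — the plain counting rule, so
#' one exceedance among 5000 permutations gives p = 2.00e-4.
#'
#' @param observed observed statistic (a nonnegative max-|correlation|).
#' @param null numeric vector of per-permutation statistics.
#' @return the empirical p-value.
#' @export
empirical_p <- function(observed, null) {
  assert_that(length(null) >= 1, "empty null sample")
  sum(null >= observed) / length(null)
}

#' Max-statistic permutation test of the inter-modality link
#'
#' Permutes the subject order of one modality (breaking the cross-modality
#' alignment while preserving each modality's internal structure), reruns
#' the parallel decomposition, and records the top absolute loading-pair
#' correlation of each run as the null sample. The observed statistic is
#' the top absolute pair correlation of the unpermuted decomposition.
#'
#' @param X1,X2 the two aligned modality matrices.
#' @param config [pica_config()] for the observed decomposition.
#' @param n_perm number of permutation runs.
#' @param perm_config optional reduced-iteration [pica_config()] used for
#'   the permutation reruns; recorded in the result.
#' @param seed RNG seed for the permutations.
#' @param observed optionally, a precomputed observed statistic (skips the
#'   observed decomposition).
#' @return a `permutation_result` with `observed`, `null`,
#'   `n_permutations`, `p`, and the profile used.
#' @export
permutation_test <- function(X1, X2, config, n_perm = 5000L,
                             perm_config = NULL, seed = 1L,
                             observed = NULL) {
  assert_that(n_perm >= 1, "n_perm must be >= 1")
  if (is.null(perm_config)) perm_config <- config
  reduced <- !identical(perm_config, config)
  if (is.null(observed)) {
    fit <- run_parallel_ica(X1, X2, config)
    observed <- max(abs(fit$pair_corr))
  }
  X2m <- mm_values(as.matrix(X2))
  n <- nrow(X2m)
  null <- with_seed(derive_seed(seed, "permutation"), {
    vapply(seq_len(n_perm), function(b) {
      perm <- sample.int(n)
      cfg <- perm_config
      cfg$seed <- derive_seed(seed, sprintf("perm-run-%d", b))
      fitb <- run_parallel_ica(X1, X2m[perm, , drop = FALSE], cfg)
      max(abs(fitb$pair_corr))
    }, numeric(1))
  })
  structure(list(observed = observed, null = null,
                 n_permutations = as.integer(n_perm),
                 p = empirical_p(observed, null),
                 reduced_profile = reduced,
                 perm_config = perm_config),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf(paste0("<permutation_result: observed %.4f vs %d-run null ",
                     "(median %.4f), p = %.3g%s>\n"),
              x$observed, x$n_permutations, median(x$null), x$p,
              if (x$reduced_profile) ", reduced-iteration profile" else ""))
  invisible(x)
}

#' Overlap ratio of a subset top-SNP set against the full-data set
#'
#' Fraction of the full-data top-weight SNP set recovered by a subset
#' decomposition's matched component.
#'
#' @param subset_top,full_top integer index sets; `full_top` nonempty.
#' @return `|intersection| / |full_top|`, in \code{[0, 1]}.
#' @export
overlap_ratio <- function(subset_top, full_top) {
  assert_that(length(full_top) > 0, "full_top must be nonempty")
  length(intersect(subset_top, full_top)) / length(full_top)
}

# Diagnosis-stratified fold assignment: within each stratum, a seeded
# shuffle followed by contiguous blocks.
stratified_folds <- function(diagnosis, k, seed) {
  dx <- factor(diagnosis)
  fold <- integer(length(dx))
  with_seed(derive_seed(seed, "folds"), {
    for (lev in levels(dx)) {
      idx <- sample(which(dx == lev))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  fold
}

#' K-fold reproducibility of the linked pair
#'
#' Repeats the parallel decomposition `k` times, each time dropping one
#' disjoint, diagnosis-stratified block of roughly `n/k` subjects. The
#' fold's components are matched to the full-data linked pair by absolute
#' correlation of component weight vectors; each fold reports the matched
#' pair's loading correlation within the fold and the overlap of its
#' top-fraction SNP set with the full-data set.
#'
#' @param X1,X2 aligned modality matrices.
#' @param config [pica_config()] used for the full run and every fold.
#' @param k number of folds (default 10).
#' @param diagnosis per-subject labels for stratification.
#' @param top_frac fraction for the top-SNP overlap (default 0.05).
#' @param seed fold-assignment seed.
#' @return list with the `full` fit, `full_top` SNP set, and `folds`, one
#'   entry per fold carrying `pair_corr`, `overlap`, `dropped`, and the
#'   matched component indices.
#' @export
kfold_reproducibility <- function(X1, X2, config, k = 10L, diagnosis,
                                  top_frac = 0.05, seed = 1L) {
  assert_that(k >= 2, "k must be >= 2")
  X1 <- mm_values(as.matrix(X1)); X2 <- mm_values(as.matrix(X2))
  full <- run_parallel_ica(X1, X2, config)
  pf <- full$constrained_pair
  full_top <- top_fraction(full$S2[pf["snp"], ], top_frac)
  fold_id <- stratified_folds(diagnosis, k, seed)
  folds <- lapply(seq_len(k), function(f) {
    keep <- which(fold_id != f)
    cfg <- config
    cfg$seed <- derive_seed(seed, sprintf("fold-%d", f))
    fit <- run_parallel_ica(X1[keep, , drop = FALSE],
                            X2[keep, , drop = FALSE], cfg)
    m1 <- which.max(abs(cor(full$S1[pf["fa"], ], t(fit$S1))))
    m2 <- which.max(abs(cor(full$S2[pf["snp"], ], t(fit$S2))))
    sub_top <- top_fraction(fit$S2[m2, ], top_frac)
    list(pair_corr = cor(fit$A1[, m1], fit$A2[, m2]),
         overlap = overlap_ratio(sub_top, full_top),
         matched = c(fa = m1, snp = m2),
         dropped = which(fold_id == f),
         n_used = length(keep))
  })
  list(full = full, full_top = full_top, folds = folds)
}

#' Re-run the analysis on a subject subgroup
#'
#' Generic subgroup re-analysis (e.g. a single-ancestry subset): the
#' parallel decomposition is repeated on the masked subjects and the top
#' pair's raw and covariate-adjusted correlations recomputed.
#'
#' @param X1,X2 aligned modality matrices.
#' @param covariates data frame with at least a `diagnosis` column; any of
#'   `site`, `ethnicity`, `age`, `sex` present are used as adjustment
#'   covariates.
#' @param subgroup_mask logical subject mask.
#' @param config [pica_config()].
#' @return list with the `fit` and the top-`pair` statistics.
#' @export
subgroup_rerun <- function(X1, X2, covariates, subgroup_mask, config) {
  X1 <- mm_values(as.matrix(X1)); X2 <- mm_values(as.matrix(X2))
  assert_that(length(subgroup_mask) == nrow(X1),
              "mask length must equal the subject count")
  idx <- which(subgroup_mask)
  cov_sub <- covariates[idx, , drop = FALSE]
  assert_that(length(unique(cov_sub$diagnosis)) == 2L,
              "subgroup must retain both diagnostic groups")
  fit <- run_parallel_ica(X1[idx, , drop = FALSE], X2[idx, , drop = FALSE],
                          config)
  pair <- linked_pair_stats(fit, cov_sub)
  list(fit = fit, pair = pair)
}

# Build the adjustment design from whichever covariates are available.
covariate_design <- function(covariates,
                             use = c("site", "ethnicity", "age", "sex")) {
  cols <- intersect(use, names(covariates))
  if (!length(cols)) return(NULL)
  parts <- lapply(cols, function(cn) {
    v <- covariates[[cn]]
    if (is.numeric(v)) matrix(v, ncol = 1, dimnames = list(NULL, cn))
    else {
      f <- factor(v)
      if (nlevels(f) < 2L) return(NULL)
      stats::model.matrix(~f)[, -1L, drop = FALSE]
    }
  })
  out <- do.call(cbind, parts[!vapply(parts, is.null, logical(1))])
  if (is.null(out) || ncol(out) == 0) NULL else out
}

#' Top-pair statistics for a decomposition
#'
#' Assembles the linked-pair record for a fitted decomposition: raw and
#' covariate-adjusted (partial) correlation of the constrained pair's
#' loading columns, with a Bonferroni flag over the full pair family.
#'
#' @param fit a `pica_result`.
#' @param covariates data frame of per-subject covariates; the adjustment
#'   set defaults to site + ethnicity + age + sex (whichever are present).
#' @param use covariate column names to adjust for.
#' @param alpha family-wise level for the Bonferroni flag.
#' @return a `linked_pair` list.
#' @export
linked_pair_stats <- function(fit, covariates,
                              use = c("site", "ethnicity", "age", "sex"),
                              alpha = 0.05) {
  pm <- pair_correlation_matrix(fit$A1, fit$A2)
  pr <- fit$constrained_pair
  a <- fit$A1[, pr["fa"]]; b <- fit$A2[, pr["snp"]]
  cd <- covariate_design(covariates, use)
  pc <- partial_correlation(a, b, cd)
  m <- length(pm$r)
  thr <- bonferroni_threshold(alpha, m)
  structure(list(fa_component = unname(pr["fa"]),
                 snp_component = unname(pr["snp"]),
                 raw_r = pm$r[pr["fa"], pr["snp"]],
                 raw_p = pm$p[pr["fa"], pr["snp"]],
                 partial_r = pc$r, partial_p = pc$p,
                 covariates_used = if (is.null(cd)) character(0) else
                   intersect(use, names(covariates)),
                 m_tests = m, bonferroni = thr,
                 passes_bonferroni = pc$p < thr,
                 pair_r = pm$r, pair_p = pm$p),
            class = "linked_pair")
}

#' @export
print.linked_pair <- function(x, ...) {
  cat(sprintf(paste0("<linked_pair: FA %d x SNP %d; raw r = %.3f (p = %.3g), ",
                     "partial r = %.3f (p = %.3g); Bonferroni %.3g over %d ",
                     "tests: %s>\n"),
              x$fa_component, x$snp_component, x$raw_r, x$raw_p,
              x$partial_r, x$partial_p, x$bonferroni, x$m_tests,
              if (x$passes_bonferroni) "pass" else "fail"))
  invisible(x)
}
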