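#' Model-order estimation by minimum description length
#'
#' Wax-Kailath MDL criterion over the eigenvalues of the subject-space
#' covariance: for each candidate signal dimension `k`, the code length is
#' the negative log of the ratio of geometric to arithmetic mean of the
#' trailing eigenvalues (a sphericity measure of the residual subspace),
#' scaled by the sample count, plus the parameter-count penalty
#' `k (2p - k) log(n) / 2`. Ties are broken toward the smaller `k`.
#'
#' @param X subjects-by-variables matrix; variables act as samples.
#' @return the minimizing component count `k` (possibly 0 for pure noise).
#' @export
estimate_ncomp_mdl <- function(X) {
  X <- mm_values(as.matrix(X))
  p <- nrow(X); n <- ncol(X)
  assert_that(n > p, "need more variables (samples) than subjects (channels)")
  Xc <- X - rowMeans(X)
  lam <- eigen(tcrossprod(Xc) / (n - 1), symmetric = TRUE,
               only.values = TRUE)$values
  lam <- pmax(lam, max(lam) * 1e-12)
  crit <- vapply(0:(p - 1L), function(k) {
    tail_ <- lam[(k + 1L):p]
    loglik <- -n * (p - k) * (mean(log(tail_)) - log(mean(tail_)))
    loglik + 0.5 * k * (2 * p - k) * log(n)
  }, numeric(1))
  which.min(crit) - 1L
}

# Mean pairwise run-to-run component similarity for one candidate k:
# components of each run pair are greedily matched by absolute correlation
# of their weight vectors and the matched |corr| values averaged.
consistency_score <- function(S_list) {
  pairs <- utils::combn(length(S_list), 2L)
  mean(apply(pairs, 2L, function(pr) {
    cm <- abs(cor(t(S_list[[pr[1L]]]), t(S_list[[pr[2L]]])))
    mean(greedy_match(cm)$corr)
  }))
}

# Greedy assignment on an absolute-correlation matrix: repeatedly pick the
# global maximum, remove its row and column. Deterministic.
greedy_match <- function(cm) {
  cm <- abs(cm)
  k <- min(dim(cm))
  rows <- integer(k); cols <- integer(k); vals <- numeric(k)
  for (i in seq_len(k)) {
    ij <- arrayInd(which.max(cm), dim(cm))
    rows[i] <- ij[1L]; cols[i] <- ij[2L]; vals[i] <- cm[ij]
    cm[ij[1L], ] <- -Inf
    cm[, ij[2L]] <- -Inf
  }
  ord <- order(rows)
  list(rows = rows[ord], cols = cols[ord], corr = vals[ord])
}

#' Model-order estimation by run-to-run component consistency
#'
#' For each candidate component count, the data are decomposed `n_runs`
#' times, each run combining a random initialization with a bootstrap
#' resample of the variables; every run's unmixing is applied back to the
#' full data, components are matched across runs by absolute correlation of
#' their weight vectors, and the mean matched correlation is the
#' consistency score. Underfitted orders retain a resample-dependent
#' subspace and overfitted orders add unstable components, so both score
#' lower than the true order. Ties are broken toward the smaller candidate.
#'
#' @param X subjects-by-variables matrix.
#' @param candidate_ks integer vector of orders to evaluate.
#' @param n_runs decompositions per candidate (>= 2; at least 5 advised).
#' @param seed master seed; each run uses a derived substream.
#' @param max_iterations iteration cap per ICA run.
#' @param bootstrap resample variables per run (default TRUE); FALSE varies
#'   only the initialization.
#' @return list with the selected `k` and the per-candidate `scores`.
#' @export
estimate_ncomp_consistency <- function(X, candidate_ks, n_runs = 10L,
                                       seed = 1L, max_iterations = 128L,
                                       bootstrap = TRUE) {
  assert_that(n_runs >= 2, "consistency is undefined for fewer than 2 runs")
  X <- mm_values(as.matrix(X))
  Xc <- X - rowMeans(X)
  scores <- vapply(candidate_ks, function(k) {
    S_list <- lapply(seq_len(n_runs), function(r) {
      run_seed <- derive_seed(seed, sprintf("consistency-%d-%d", k, r))
      with_seed(run_seed, {
        Xb <- if (bootstrap)
          X[, sample.int(ncol(X), replace = TRUE), drop = FALSE] else X
        red <- pca_reduce(Xb, k)
        fit <- infomax_fit(red$Xw, learning_rate = 0.3,
                           max_iterations = max_iterations,
                           anneal_factor = 0.9, convergence_tol = 1e-6,
                           W = random_orthonormal(k))
        S_full <- (fit$W %*% red$K) %*% Xc
        S_full / apply(S_full, 1L, sd)
      })
    })
    consistency_score(S_list)
  }, numeric(1))
  best <- candidate_ks[which.max(scores)]  # which.max takes the first max
  list(k = best, scores = stats::setNames(scores, candidate_ks))
}
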