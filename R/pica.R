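#' Decomposition settings for parallel ICA
#'
#' Bundles every tunable of the joint decomposition. Defaults follow the
#' reference configuration of the method: at most one constrained component
#' pair, a correlation threshold of 0.3 before the constraint activates, and
#' an endurance of -1e-5 bounding the admissible per-iteration decrease of
#' the infomax entropy term while the constraint is running.
#'
#' @param n_comp_fa,n_comp_snp number of components retained per modality.
#' @param learning_rate initial infomax natural-gradient step size.
#' @param max_iterations iteration cap.
#' @param constraint_threshold absolute loading correlation above which the
#'   correlation-enhancement step is applied (default 0.3).
#' @param max_constrained_pairs number of loading pairs eligible for
#'   enhancement (default 1).
#' @param endurance negative bound on the per-iteration entropy decrease
#'   tolerated while the constraint is active (default -1e-5); a steeper
#'   drop suspends the constraint for the iteration and halves its rate.
#' @param anneal_factor learning-rate multiplier applied whenever the
#'   entropy surrogate decreases (default 0.9).
#' @param convergence_tol relative unmixing-weight change declaring
#'   convergence (default 1e-6).
#' @param constraint_rate step-size multiplier for the correlation
#'   enhancement gradient (scaled internally by the subject count).
#' @param seed integer seed controlling the random orthonormal
#'   initialization of both unmixing matrices.
#' @return a `pica_config` list.
#' @export
pica_config <- function(n_comp_fa, n_comp_snp,
                        learning_rate = 0.3,
                        max_iterations = 512L,
                        constraint_threshold = 0.3,
                        max_constrained_pairs = 1L,
                        endurance = -1e-5,
                        anneal_factor = 0.9,
                        convergence_tol = 1e-6,
                        constraint_rate = 0.1,
                        seed = 1L) {
  assert_that(constraint_threshold >= 0 && constraint_threshold <= 1,
              "constraint_threshold must lie in [0, 1]")
  assert_that(endurance < 0, "endurance must be negative")
  assert_that(anneal_factor > 0 && anneal_factor < 1,
              "anneal_factor must lie in (0, 1)")
  assert_that(n_comp_fa >= 1 && n_comp_snp >= 1, "component counts must be >= 1")
  structure(list(n_comp_fa = as.integer(n_comp_fa),
                 n_comp_snp = as.integer(n_comp_snp),
                 learning_rate = learning_rate,
                 max_iterations = as.integer(max_iterations),
                 constraint_threshold = constraint_threshold,
                 max_constrained_pairs = as.integer(max_constrained_pairs),
                 endurance = endurance,
                 anneal_factor = anneal_factor,
                 convergence_tol = convergence_tol,
                 constraint_rate = constraint_rate,
                 seed = as.integer(seed)),
            class = "pica_config")
}

#' PCA reduction and whitening along the subject dimension
#'
#' Projects a subjects-by-variables matrix onto its top `k` subject-space
#' principal directions and whitens them, so that the subsequent unmixing
#' matrix is square and invertible. Rows are centered (each subject's mean
#' across variables removed) before the eigendecomposition.
#'
#' @param X subjects-by-variables numeric matrix.
#' @param k number of retained dimensions; must not exceed the rank.
#' @return list with `Xw` (k-by-variables whitened data, unit row
#'   covariance), `K` (k-by-subjects whitening map), `D`
#'   (subjects-by-k dewhitening map satisfying `K %*% D = I`), `row_means`,
#'   and the eigenvalues `values`.
#' @export
pca_reduce <- function(X, k) {
  X <- mm_values(as.matrix(X))
  n <- nrow(X); v <- ncol(X)
  assert_that(k >= 1 && k <= min(n, v), "k must lie in [1, min(dim)]")
  rm_ <- rowMeans(X)
  Xc <- X - rm_
  C <- tcrossprod(Xc) / (v - 1)
  e <- eigen(C, symmetric = TRUE)
  tol <- max(e$values) * 1e-10
  assert_that(e$values[k] > tol, "k exceeds the numerical rank of the data")
  U <- e$vectors[, seq_len(k), drop = FALSE]
  d <- e$values[seq_len(k)]
  K <- t(U) / sqrt(d)        # k x n
  D <- U * rep(sqrt(d), each = n)  # n x k, K %*% D = I
  list(Xw = K %*% Xc, K = K, D = D, row_means = rm_, values = e$values)
}

# Infomax entropy surrogate: log|det W| + mean over samples of
# sum_i log(y_i (1 - y_i)), the differential entropy of the logistic-squashed
# output up to an additive constant.
infomax_entropy <- function(W, W0, X) {
  U <- W %*% X + W0
  Y <- 1 / (1 + exp(-U))
  ld <- determinant(W, logarithm = TRUE)$modulus[1]
  ld + mean(colSums(log(pmax(Y * (1 - Y), .Machine$double.xmin))))
}

#' One infomax natural-gradient update
#'
#' Applies a single step of the natural-gradient rule for the logistic
#' nonlinearity: with `U = W X + W0` and `Y = 1/(1+exp(-U))`,
#' `W <- W + lr (I + (1-2Y) U'/m) W` and `W0 <- W0 + lr mean(1-2Y)`, where
#' `m` is the number of samples (columns).
#'
#' @param W square unmixing matrix (k-by-k).
#' @param W0 bias vector (length k).
#' @param X k-by-samples data batch (whitened).
#' @param learning_rate step size; 0 leaves parameters untouched.
#' @return list with updated `W`, `W0`, and `ok` (FALSE when the step
#'   produced non-finite values and was rejected).
#' @export
infomax_update <- function(W, W0, X, learning_rate) {
  assert_that(nrow(W) == ncol(W), "W must be square")
  m <- ncol(X)
  U <- W %*% X + W0
  Y <- 1 / (1 + exp(-U))
  G <- diag(nrow(W)) + tcrossprod(1 - 2 * Y, U) / m
  Wn <- W + learning_rate * G %*% W
  W0n <- W0 + learning_rate * rowMeans(1 - 2 * Y)
  if (!all(is.finite(Wn)) || !all(is.finite(W0n))) {
    return(list(W = W, W0 = W0, ok = FALSE))
  }
  list(W = Wn, W0 = W0n, ok = TRUE)
}

# Analytic gradient of squared Pearson correlation wrt both vectors.
corr2_grad <- function(a, b) {
  n <- length(a)
  assert_that(n >= 3 && length(b) == n, "columns must have equal length >= 3")
  va <- var(a); vb <- var(b)
  assert_that(va > 0 && vb > 0, "zero-variance column in constraint update")
  cab <- cov(a, b)
  ac <- a - mean(a); bc <- b - mean(b)
  ga <- (2 * cab / (va * vb)) * bc / (n - 1) -
    (cab^2 / (va^2 * vb)) * 2 * ac / (n - 1)
  gb <- (2 * cab / (va * vb)) * ac / (n - 1) -
    (cab^2 / (va * vb^2)) * 2 * bc / (n - 1)
  list(ga = ga, gb = gb)
}

#' Correlation-enhancement step for one loading pair
#'
#' Gradient-ascent step on the squared Pearson correlation between two
#' subject-loading columns — the cross-modality term added to the two
#' entropy terms in the joint objective. The closed-form gradient preserves
#' the sign of the correlation: an anti-correlated pair is pushed toward
#' stronger anti-correlation.
#'
#' @param a1_col,a2_col loading columns of equal length (>= 3 subjects).
#' @param learning_rate step multiplier applied to the raw gradient.
#' @return list with increments `d1` and `d2` for the two columns.
#' @export
constraint_update <- function(a1_col, a2_col, learning_rate) {
  g <- corr2_grad(a1_col, a2_col)
  list(d1 = learning_rate * g$ga, d2 = learning_rate * g$gb)
}

# Random orthonormal k x k matrix (QR of a Gaussian matrix, sign-fixed).
random_orthonormal <- function(k) {
  qrd <- qr(matrix(rnorm(k * k), k, k))
  Q <- qr.Q(qrd)
  Q * rep(sign(diag(qr.R(qrd))), each = k)
}

# Single-modality infomax loop on whitened data. Returns W, W0 and history.
infomax_fit <- function(Xw, learning_rate, max_iterations, anneal_factor,
                        convergence_tol, W = NULL, W0 = NULL) {
  k <- nrow(Xw)
  if (is.null(W)) W <- random_orthonormal(k)
  if (is.null(W0)) W0 <- numeric(k)
  lr <- learning_rate
  hist_H <- numeric(0)
  prev_H <- -Inf
  converged <- FALSE
  for (t in seq_len(max_iterations)) {
    H <- infomax_entropy(W, W0, Xw)
    if (H < prev_H) lr <- lr * anneal_factor
    prev_H <- H
    hist_H <- c(hist_H, H)
    st <- infomax_update(W, W0, Xw, lr)
    if (!st$ok) { lr <- lr * anneal_factor; next }
    dw <- norm(st$W - W, "F") / max(norm(W, "F"), 1e-12)
    W <- st$W; W0 <- st$W0
    if (dw < convergence_tol) { converged <- TRUE; break }
  }
  list(W = W, W0 = W0, entropy = hist_H, converged = converged, iterations = t)
}

# Standardize component rows to unit variance, absorb scale into loadings,
# and fix signs so each component's largest-|weight| element is positive.
standardize_components <- function(S, A) {
  sds <- apply(S, 1L, sd)
  sds[sds == 0] <- 1
  S <- S / sds
  A <- A * rep(sds, each = nrow(A))
  for (r in seq_len(nrow(S))) {
    if (S[r, which.max(abs(S[r, ]))] < 0) {
      S[r, ] <- -S[r, ]
      A[, r] <- -A[, r]
    }
  }
  list(S = S, A = A)
}

#' Run parallel ICA on two modalities
#'
#' Alternates full-batch infomax natural-gradient passes over the two
#' modalities. After each pass the subject-space loading matrices are
#' recomputed and the loading pair with the highest absolute correlation is
#' found; when that correlation exceeds `constraint_threshold`, a
#' gradient-ascent step on the squared correlation is applied to the pair
#' (at most `max_constrained_pairs` pairs) and propagated back to the
#' unmixing matrix through the inverse relationship `W = A^-1` in the
#' whitened space. If an iteration's entropy drop is steeper than
#' `endurance` while the constraint is active, the constraint is suspended
#' for that iteration and its rate halved. The learning rate of a modality
#' is annealed whenever its entropy surrogate decreases.
#'
#' @param X1 FA modality, subjects-by-voxels matrix (or [modality_matrix()]).
#' @param X2 SNP modality, subjects-by-SNPs matrix, same subject order.
#' @param config a [pica_config()].
#' @return a `pica_result` with subject-space loadings `A1`, `A2`,
#'   unit-variance sign-fixed components `S1`, `S2`, unmixing matrices and
#'   biases, entropy and constraint-correlation histories, the constrained
#'   pair, and a convergence flag.
#' @export
run_parallel_ica <- function(X1, X2, config) {
  X1 <- mm_values(as.matrix(X1)); X2 <- mm_values(as.matrix(X2))
  n <- nrow(X1)
  assert_that(nrow(X2) == n, "modalities must share subject order")
  assert_that(config$n_comp_fa <= n && config$n_comp_snp <= n,
              "component counts cannot exceed the subject count")
  r1 <- pca_reduce(X1, config$n_comp_fa)
  r2 <- pca_reduce(X2, config$n_comp_snp)

  st <- with_seed(config$seed, list(W1 = random_orthonormal(config$n_comp_fa),
                                    W2 = random_orthonormal(config$n_comp_snp)))
  W1 <- st$W1; W2 <- st$W2
  W01 <- numeric(config$n_comp_fa); W02 <- numeric(config$n_comp_snp)
  lr1 <- lr2 <- config$learning_rate
  crate <- config$constraint_rate * (n - 1)
  H1_prev <- H2_prev <- -Inf
  hist_H <- matrix(NA_real_, config$max_iterations, 2L,
                   dimnames = list(NULL, c("fa", "snp")))
  hist_corr <- rep(NA_real_, config$max_iterations)
  hist_active <- rep(FALSE, config$max_iterations)
  constraint_prev <- FALSE
  converged <- FALSE
  pair <- c(NA_integer_, NA_integer_)

  for (t in seq_len(config$max_iterations)) {
    W1_old <- W1; W2_old <- W2
    H1 <- infomax_entropy(W1, W01, r1$Xw)
    H2 <- infomax_entropy(W2, W02, r2$Xw)
    hist_H[t, ] <- c(H1, H2)
    if (H1 < H1_prev) lr1 <- lr1 * config$anneal_factor
    if (H2 < H2_prev) lr2 <- lr2 * config$anneal_factor
    # endurance: a steep entropy drop while the constraint is running
    # suspends it for this iteration and halves its rate
    suspend <- constraint_prev &&
      ((H1 - H1_prev) < config$endurance || (H2 - H2_prev) < config$endurance)
    if (suspend) crate <- crate / 2
    H1_prev <- H1; H2_prev <- H2

    s1 <- infomax_update(W1, W01, r1$Xw, lr1)
    if (s1$ok) { W1 <- s1$W; W01 <- s1$W0 } else lr1 <- lr1 * config$anneal_factor
    s2 <- infomax_update(W2, W02, r2$Xw, lr2)
    if (s2$ok) { W2 <- s2$W; W02 <- s2$W0 } else lr2 <- lr2 * config$anneal_factor

    # subject-space loadings and the current best pair; a singular W means
    # the last step was too aggressive -- roll it back and anneal
    A1r <- try(solve(W1), silent = TRUE)
    A2r <- try(solve(W2), silent = TRUE)
    if (inherits(A1r, "try-error") || inherits(A2r, "try-error")) {
      W1 <- W1_old; W2 <- W2_old
      lr1 <- lr1 * config$anneal_factor
      lr2 <- lr2 * config$anneal_factor
      next
    }
    A1 <- r1$D %*% A1r
    A2 <- r2$D %*% A2r
    cm <- suppressWarnings(cor(A1, A2))
    cm[!is.finite(cm)] <- 0
    ij <- arrayInd(which.max(abs(cm)), dim(cm))
    pair <- c(ij[1L], ij[2L])
    hist_corr[t] <- cm[ij]

    constraint_prev <- FALSE
    if (config$max_constrained_pairs >= 1L && !suspend &&
        abs(cm[ij]) > config$constraint_threshold) {
      upd <- constraint_update(A1[, pair[1L]], A2[, pair[2L]], crate)
      A1[, pair[1L]] <- A1[, pair[1L]] + upd$d1
      A2[, pair[2L]] <- A2[, pair[2L]] + upd$d2
      W1n <- try(solve(r1$K %*% A1), silent = TRUE)
      W2n <- try(solve(r2$K %*% A2), silent = TRUE)
      if (!inherits(W1n, "try-error") && !inherits(W2n, "try-error")) {
        W1 <- W1n
        W2 <- W2n
        constraint_prev <- TRUE
        hist_active[t] <- TRUE
      } else {
        crate <- crate / 2  # degenerate constraint step; back off
      }
    }

    dw1 <- norm(W1 - W1_old, "F") / max(norm(W1_old, "F"), 1e-12)
    dw2 <- norm(W2 - W2_old, "F") / max(norm(W2_old, "F"), 1e-12)
    if (max(dw1, dw2) < config$convergence_tol) { converged <- TRUE; break }
  }

  S1 <- W1 %*% r1$Xw
  S2 <- W2 %*% r2$Xw
  z1 <- standardize_components(S1, r1$D %*% solve(W1))
  z2 <- standardize_components(S2, r2$D %*% solve(W2))
  cm <- cor(z1$A, z2$A)
  ij <- arrayInd(which.max(abs(cm)), dim(cm))
  subj <- rownames(X1)
  if (!is.null(subj)) { rownames(z1$A) <- subj; rownames(z2$A) <- subj }
  colnames(S1) <- colnames(X1); colnames(S2) <- colnames(X2)

  structure(list(
    A1 = z1$A, A2 = z2$A, S1 = z1$S, S2 = z2$S,
    W1 = W1, W2 = W2, W01 = W01, W02 = W02,
    whitening = list(K1 = r1$K, D1 = r1$D, K2 = r2$K, D2 = r2$D,
                     row_means1 = r1$row_means, row_means2 = r2$row_means),
    entropy_history = hist_H[seq_len(t), , drop = FALSE],
    corr_history = hist_corr[seq_len(t)],
    constraint_active = hist_active[seq_len(t)],
    constrained_pair = c(fa = ij[1L], snp = ij[2L]),
    constrained_corr = cm[ij],
    pair_corr = cm,
    converged = converged,
    iterations = t,
    config = config
  ), class = "pica_result")
}

#' @export
print.pica_result <- function(x, ...) {
  cat(sprintf(paste0("<pica_result: %d FA x %d SNP components, %d subjects>\n",
                     "  constrained pair (%d, %d): r = %.3f; %s after %d iterations\n"),
              nrow(x$S1), nrow(x$S2), nrow(x$A1),
              x$constrained_pair[1L], x$constrained_pair[2L],
              x$constrained_corr,
              if (x$converged) "converged" else "NOT converged", x$iterations))
  invisible(x)
}

#' Single-modality infomax ICA
#'
#' Plain infomax decomposition of one subjects-by-variables matrix: the
#' parallel algorithm with the cross-modality constraint absent. Used for
#' run-to-run consistency model-order estimation and as a baseline.
#'
#' @param X subjects-by-variables matrix.
#' @param k number of components.
#' @param learning_rate,max_iterations,anneal_factor,convergence_tol as in
#'   [pica_config()].
#' @param seed RNG seed for the orthonormal initialization.
#' @return list with `S` (k-by-variables, unit variance, sign-fixed), `A`
#'   (subjects-by-k), `W`, `W0`, `converged`, `iterations`.
#' @export
run_infomax <- function(X, k, learning_rate = 0.1, max_iterations = 256L,
                        anneal_factor = 0.9, convergence_tol = 1e-6,
                        seed = 1L) {
  X <- mm_values(as.matrix(X))
  r <- pca_reduce(X, k)
  W <- with_seed(seed, random_orthonormal(k))
  fit <- infomax_fit(r$Xw, learning_rate, max_iterations, anneal_factor,
                     convergence_tol, W = W)
  S <- fit$W %*% r$Xw
  z <- standardize_components(S, r$D %*% solve(fit$W))
  list(S = z$S, A = z$A, W = fit$W, W0 = fit$W0,
       converged = fit$converged, iterations = fit$iterations,
       entropy = fit$entropy)
}
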