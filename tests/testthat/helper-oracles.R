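# Independent oracles and small fixtures used across the suite.

# Amari index between an estimated and a true mixing: 0 for a perfect
# separation up to permutation and scale, 1-ish for unrelated matrices.
amari_index <- function(P) {
  P <- abs(P)
  k <- nrow(P)
  r <- sum(rowSums(P / apply(P, 1L, max)) - 1)
  c <- sum(colSums(t(t(P) / apply(P, 2L, max))) - 1)
  (r + c) / (2 * k * (k - 1))
}

# Exact HWE p-value by the heterozygote-count recurrence (an independent
# route: probabilities built multiplicatively from a starting value rather
# than from log-factorials).
hwe_oracle <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  rare <- min(2 * n_AA + n_Aa, 2 * n_aa + n_Aa)
  hs <- seq.int(rare %% 2L, min(rare, 2L * n - rare), by = 2L)
  pr <- numeric(length(hs))
  mid <- which.min(abs(hs - rare * (2 * n - rare) / (2 * n)))
  pr[mid] <- 1
  if (mid < length(hs)) {
    for (i in mid:(length(hs) - 1L)) {
      h <- hs[i]
      rh <- (rare - h) / 2
      ch <- n - (rare + h) / 2
      pr[i + 1L] <- pr[i] * 4 * rh * ch / ((h + 2) * (h + 1))
    }
  }
  if (mid > 1L) {
    for (i in mid:2L) {
      h <- hs[i]
      rh <- (rare - h) / 2
      ch <- n - (rare + h) / 2
      pr[i - 1L] <- pr[i] * h * (h - 1) / (4 * (rh + 1) * (ch + 1))
    }
  }
  pr <- pr / sum(pr)
  obs <- pr[match(n_Aa, hs)]
  min(1, sum(pr[pr <= obs * (1 + 1e-9)]))
}

# Central-difference numerical gradient of a scalar function of a matrix or
# vector argument.
num_grad <- function(f, x, eps = 1e-6) {
  g <- x
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    g[i] <- (f(xp) - f(xm)) / (2 * eps)
  }
  g
}

# Entropy surrogate of the logistic infomax model, written independently of
# the package internals (explicit loops over samples are avoided but the
# algebra is restated from scratch).
entropy_surrogate <- function(W, W0, X) {
  U <- W %*% X + as.numeric(W0)
  Y <- 1 / (1 + exp(-U))
  as.numeric(determinant(W, logarithm = TRUE)$modulus) +
    mean(colSums(log(Y * (1 - Y))))
}

# Mixture of sparse super-Gaussian sources: S k x m (cubed Gaussians),
# A n x k, X = A S.
super_gaussian_mix <- function(n_src, n_mix, m, seed) {
  set.seed(seed)
  S <- matrix(rnorm(n_src * m)^3, n_src, m)
  A <- matrix(rnorm(n_mix * n_src), n_mix, n_src)
  list(X = A %*% S, A = A, S = S)
}

# Small linked-cohort configuration for fast end-to-end tests.
small_config <- function(seed = 1L, ...) {
  synth_config(n_cases = 33L, n_controls = 27L, n_voxels = 300L,
               n_snps = 200L, n_components_fa = 3L, n_components_snp = 3L,
               seed = seed, ...)
}

# Reduced-iteration decomposition profile for permutation-scale work.
reduced_profile <- function(k1 = 3L, k2 = 3L, seed = 1L) {
  pica_config(k1, k2, max_iterations = 30L, seed = seed)
}
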