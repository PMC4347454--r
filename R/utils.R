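#' @keywords internal
"_PACKAGE"

#' @importFrom stats anova aov coef cor cor.test lm lm.fit median pchisq
#'   pf prcomp pt qnorm quantile rbinom rnorm runif sd t.test var
#' @importFrom utils head read.table write.table
NULL

# Derive a reproducible substream seed from a master seed and a stage label.
# Keeps all derived seeds inside the 32-bit integer range.
derive_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(seed) * 2654435.0 + h * 97.0) %% 2147483629) + 1L
}

# Run an expression with a locally-set RNG seed, restoring global RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

assert_that <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
  invisible(TRUE)
}

# Column-standardize a vector (sample sd); errors on zero variance.
std1 <- function(x) {
  s <- sd(x)
  assert_that(s > 0, "zero-variance vector cannot be standardized")
  (x - mean(x)) / s
}
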