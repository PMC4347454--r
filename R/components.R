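#' Z-score a component weight vector
#'
#' Centers and scales a component row to mean 0 and unit standard
#' deviation, the form in which spatial maps and SNP weight vectors are
#' thresholded.
#'
#' @param s numeric vector of component weights.
#' @return the z-scored vector.
#' @export
zscore_component <- function(s) {
  assert_that(length(s) >= 2, "component must have at least 2 weights")
  std1(as.numeric(s))
}

#' Threshold a z-scored component
#'
#' Returns the indices of variables whose absolute z-scored weight strictly
#' exceeds `z_min` (default 3.5, the conventional cutoff for displaying the
#' supra-threshold part of a component map).
#'
#' @param z z-scored weight vector.
#' @param z_min strict absolute threshold.
#' @return integer index set (possibly empty).
#' @export
threshold_component <- function(z, z_min = 3.5) {
  which(abs(as.numeric(z)) > z_min)
}

#' Top fraction of a weight vector by absolute value
#'
#' Selects the `floor(fraction * length)` variables with the largest
#' absolute weights — e.g. the top 5% of 6527 SNP weights is a set of 326
#' SNPs. Ties across the cut are broken deterministically by ascending
#' index.
#'
#' @param weights numeric weight vector.
#' @param fraction fraction in (0, 1].
#' @return integer index set in ascending order.
#' @export
top_fraction <- function(weights, fraction = 0.05) {
  assert_that(fraction > 0 && fraction <= 1, "fraction must lie in (0, 1]")
  m <- floor(fraction * length(weights))
  if (m == 0L) return(integer(0))
  ord <- order(-abs(weights), seq_along(weights))
  sort(ord[seq_len(m)])
}
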