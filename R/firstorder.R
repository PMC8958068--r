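#' First-order intensity features
#'
#' Sixteen features computed from the raw (undiscretized) HU values of the
#' resegmented ROI, plus entropy and uniformity computed from the discretized
#' histogram. Because only entropy and uniformity see the discretized data,
#' the other sixteen are bit-identical across bin widths.
#'
#' Conventions: kurtosis is Pearson (no -3 offset); total energy is voxel
#' volume times the sum of squared intensities; the robust mean absolute
#' deviation uses the closed percentile interval [P10, P90]; percentiles use
#' linear interpolation; moments are population moments; skewness and
#' kurtosis of a constant ROI are 0 by convention.
#'
#' @param image a [volume_grid] on the analysis grid.
#' @param mask the resegmented [roi_mask].
#' @param d the matching [discretize()] result (for entropy/uniformity).
#' @return Named numeric vector of the 18 `firstorder_*` features.
#' @export
firstorder_features <- function(image, mask, d) {
  check_same_grid(image, mask)
  stopifnot(inherits(d, "discretized_roi"))
  x <- image$values[mask$values == 1L]
  n <- length(x)
  mu <- mean(x)
  m2 <- mean((x - mu)^2)
  m3 <- mean((x - mu)^3)
  m4 <- mean((x - mu)^4)
  q <- quantile(x, c(0.10, 0.25, 0.75, 0.90), names = FALSE, type = 7)
  sub <- x[x >= q[1] & x <= q[4]]
  rmad <- if (length(sub) > 0) mean(abs(sub - mean(sub))) else 0

  lev <- d$levels[d$levels > 0L]
  p <- tabulate(lev, nbins = d$n_levels) / length(lev)
  pp <- p[p > 0]

  c(firstorder_10_percentile = q[1],
    firstorder_90_percentile = q[4],
    firstorder_energy = sum(x^2),
    firstorder_entropy = -sum(pp * log2(pp)),
    firstorder_interquartile_range = q[3] - q[2],
    firstorder_kurtosis = if (m2 > 0) m4 / m2^2 else 0,
    firstorder_maximum = max(x),
    firstorder_mean_absolute_deviation = mean(abs(x - mu)),
    firstorder_mean = mu,
    firstorder_median = median(x),
    firstorder_minimum = min(x),
    firstorder_range = max(x) - min(x),
    firstorder_robust_mean_absolute_deviation = rmad,
    firstorder_root_mean_squared = sqrt(mean(x^2)),
    firstorder_skewness = if (m2 > 0) m3 / m2^1.5 else 0,
    firstorder_total_energy = d$voxel_volume * sum(x^2),
    firstorder_uniformity = sum(p^2),
    firstorder_variance = m2)
}
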