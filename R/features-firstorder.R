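# First-order (histogram) features. Location statistics (mean, median, RMS,
# percentiles) are computed on the raw intensities; entropy and uniformity
# on the fixed-bin-width discretized levels, matching the convention of the
# standard radiomics toolchain. Percentiles and the median use linear
# interpolation between order statistics (stats::quantile type 7).

#' First-order radiomic features
#'
#' Computes the 18 first-order features of the canonical set: energy, total
#' energy, entropy, kurtosis, maximum, minimum, mean, median, interquartile
#' range, skewness, range, mean absolute deviation (MAD), robust MAD (mean
#' absolute deviation of the values between the 10th and 90th percentile),
#' root mean squared (RMS), variance, uniformity, and the 10th and 90th
#' percentiles. Variance and the standardized moments use population (1/N)
#' divisors; kurtosis is not excess-corrected (a Gaussian gives 3).
#' Degenerate conventions for a constant sample: skewness and kurtosis are
#' 0, entropy 0, uniformity 1.
#'
#' @param values Numeric intensity sample (non-empty).
#' @param voxel_volume Physical volume of one voxel in mm^3 (used by total
#'   energy).
#' @param bin_width Bin width for the discretization behind entropy and
#'   uniformity.
#' @return Named numeric vector of 18 features, names prefixed
#'   `firstorder_`.
#' @examples
#' first_order_features(c(1, 2, 3, 4), voxel_volume = 1)[c("firstorder_mean",
#'   "firstorder_rms")]
#' @export
first_order_features <- function(values, voxel_volume = 1, bin_width = 25) {
  if (length(values) == 0L) .stopf("first-order features need a non-empty sample")
  n <- length(values)
  mu <- mean(values)
  m2 <- mean((values - mu)^2)
  m3 <- mean((values - mu)^3)
  m4 <- mean((values - mu)^4)
  q <- stats::quantile(values, c(0.10, 0.25, 0.50, 0.75, 0.90),
                       names = FALSE, type = 7)
  inner <- values[values >= q[1L] & values <= q[5L]]
  rmad <- if (length(inner) > 0L) mean(abs(inner - mean(inner))) else 0
  lev <- discretize_fixed_bin_width(values, bin_width = bin_width)
  p <- tabulate(lev$levels_vec, lev$ng) / n
  p <- p[p > 0]
  energy <- sum(values^2)
  c(firstorder_energy = energy,
    firstorder_total_energy = voxel_volume * energy,
    firstorder_entropy = -sum(p * log2(p)),
    firstorder_kurtosis = if (m2 > 0) m4 / m2^2 else 0,
    firstorder_maximum = max(values),
    firstorder_minimum = min(values),
    firstorder_mean = mu,
    firstorder_median = q[3L],
    firstorder_iqr = q[4L] - q[2L],
    firstorder_skewness = if (m2 > 0) m3 / m2^1.5 else 0,
    firstorder_range = max(values) - min(values),
    firstorder_mad = mean(abs(values - mu)),
    firstorder_rmad = rmad,
    firstorder_rms = sqrt(mean(values^2)),
    firstorder_variance = m2,
    firstorder_uniformity = sum(p^2),
    firstorder_p10 = q[1L],
    firstorder_p90 = q[5L])
}
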