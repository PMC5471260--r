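#' First-order intensity statistics
#'
#' Computes 12 statistics of the in-mask intensities: energy, histogram
#' entropy, excess kurtosis, maximum, mean, mean absolute deviation, median,
#' minimum, range, root mean square, skewness and standard deviation.
#' Moments use population normalization (divide by n); skewness and kurtosis
#' are declared undefined (NaN, with a message) on constant regions. Entropy
#' uses a fixed-width histogram anchored at the in-mask minimum
#' (`bin_width_hu`, default 25 HU), matching the texture discretization.
#'
#' @param volume a [voxel_volume()] (or filtered image).
#' @param mask an aligned [region_mask()].
#' @param bin_width_hu histogram bin width for the entropy feature.
#' @return Named numeric vector of 12 features.
#' @export
intensity_statistics <- function(volume, mask, bin_width_hu = 25) {
  check_aligned(volume, mask)
  check_nonempty_mask(mask)
  x <- volume$intensities[mask$voxels]
  if (any(!is.finite(x))) stop("non-finite intensities inside the mask")
  n <- length(x)
  mu <- mean(x)
  m2 <- mean((x - mu)^2)
  sdev <- sqrt(m2)
  if (m2 > 0) {
    skew <- mean((x - mu)^3) / m2^1.5
    kurt <- mean((x - mu)^4) / m2^2 - 3
  } else {
    message("constant region: skewness/kurtosis undefined (NaN)")
    skew <- NaN
    kurt <- NaN
  }
  lev <- as.integer(floor((x - min(x)) / bin_width_hu)) + 1L
  p <- tabulate(lev) / n
  p <- p[p > 0]
  c(energy = sum(x^2),
    entropy = -sum(p * log2(p)),
    kurtosis = kurt,
    maximum = max(x),
    mean = mu,
    mean_absolute_deviation = mean(abs(x - mu)),
    median = stats::median(x),
    minimum = min(x),
    range = max(x) - min(x),
    root_mean_square = sqrt(mean(x^2)),
    skewness = skew,
    standard_deviation = sdev)
}
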