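#' First-order intensity features
#'
#' The 17 first-order descriptors of the in-mask intensity distribution:
#' energy `sum((X + c)^2)`, total energy (energy scaled by the voxel volume
#' in mm^3), entropy (over the discretized gray levels), minimum, 10th and
#' 90th percentiles, maximum, mean, median, interquartile range (P75 - P25),
#' range, mean absolute deviation, robust mean absolute deviation (over the
#' P10-P90 subset), root mean squared, skewness, kurtosis (plain fourth
#' standardized moment, not excess) and variance (population). Skewness and
#' kurtosis of a flat region fall back to 0, flagged.
#'
#' @param image numeric 3D intensity array.
#' @param mask logical 3D array on the same grid.
#' @param spacing_mm per-axis voxel spacing in mm.
#' @param settings discretization settings (for the entropy histogram).
#' @param c_shift optional intensity shift `c` applied in energy-type
#'   features; default 0.
#' @return Named numeric vector of 17 features with a `flags` attribute.
#' @export
first_order_features <- function(image, mask, spacing_mm = c(1, 1, 1),
                                 settings = extraction_settings(),
                                 c_shift = 0) {
  mask <- array(as.logical(mask), dim(mask))
  if (!identical(dim(image), dim(mask)))
    stop("image and mask must share the same grid")
  if (!any(mask)) stop("mask is empty")
  x <- as.numeric(image[mask])
  np <- length(x)
  voxvol <- prod(spacing_mm)
  mu <- mean(x)
  m2 <- mean((x - mu)^2)
  m3 <- mean((x - mu)^3)
  m4 <- mean((x - mu)^4)
  q <- unname(quantile(x, c(0.10, 0.25, 0.75, 0.90), type = 7))
  rob <- x[x >= q[1] & x <= q[4]]
  lev <- quantize(image, mask, settings, spacing_mm)$levels[mask]
  p <- tabulate(lev) / np
  entropy <- -sum(xlog2x(p))
  energy <- sum((x + c_shift)^2)
  out <- c(
    Energy = energy,
    TotalEnergy = voxvol * energy,
    Entropy = entropy,
    Minimum = min(x),
    Percentile10 = q[1],
    Percentile90 = q[4],
    Maximum = max(x),
    Mean = mu,
    Median = median(x),
    InterquartileRange = q[3] - q[2],
    Range = max(x) - min(x),
    MeanAbsoluteDeviation = mean(abs(x - mu)),
    RobustMeanAbsoluteDeviation = mean(abs(rob - mean(rob))),
    RootMeanSquared = sqrt(mean((x + c_shift)^2)),
    Skewness = if (m2 > 0) m3 / m2^1.5 else NA_real_,
    Kurtosis = if (m2 > 0) m4 / m2^2 else NA_real_,
    Variance = m2
  )
  sanitize_features(out, fallbacks = list(Skewness = 0, Kurtosis = 0))
}
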