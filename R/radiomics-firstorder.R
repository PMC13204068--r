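#' First-order (intensity histogram) features
#'
#' Computed from the resegmented in-ROI intensities; Entropy and Uniformity
#' use the fixed-bin-width discretized histogram, Entropy in bits.
#'
#' @param sample An [rad_preprocess()] ROI sample.
#' @return Named numeric vector with `firstorder_` prefixed names: Mean,
#'   Median, Minimum, Maximum, Range, Variance, Skewness, Kurtosis,
#'   Energy (sum of squared HU), TotalEnergy (voxel volume times Energy),
#'   RootMeanSquared, MeanAbsoluteDeviation, InterquartileRange,
#'   Percentile10, Percentile90, Entropy (bits), Uniformity.
#' @export
rad_first_order <- function(sample) {
  x <- sample$intensities
  n <- length(x)
  stopifnot(n >= 1)
  voxvol <- prod(sample$spacing)
  mu <- mean(x)
  v <- mean((x - mu)^2)          # population variance, histogram convention
  sdv <- sqrt(v)
  skew <- if (sdv > 0) mean((x - mu)^3) / sdv^3 else 0
  kurt <- if (sdv > 0) mean((x - mu)^4) / sdv^4 else 0
  p <- tabulate(sample$bins) / n
  p <- p[p > 0]
  q <- stats::quantile(x, c(0.10, 0.25, 0.5, 0.75, 0.90), names = FALSE,
                       type = 7)
  feats <- c(
    Mean = mu,
    Median = q[3],
    Minimum = min(x),
    Maximum = max(x),
    Range = max(x) - min(x),
    Variance = v,
    Skewness = skew,
    Kurtosis = kurt,
    Energy = sum(x^2),
    TotalEnergy = voxvol * sum(x^2),
    RootMeanSquared = sqrt(mean(x^2)),
    MeanAbsoluteDeviation = mean(abs(x - mu)),
    InterquartileRange = q[4] - q[2],
    Percentile10 = q[1],
    Percentile90 = q[5],
    Entropy = -sum(p * log2(p)),
    Uniformity = sum(p^2)
  )
  stats::setNames(feats, paste0("firstorder_", names(feats)))
}
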