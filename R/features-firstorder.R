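#' First-order (gray-level distribution) features
#'
#' The 19 first-order statistics of the IBSI reference set, computed on
#' the raw patch intensities. Entropy and uniformity are computed on the
#' `Ng`-bin fixed-bin-count discretisation of the patch; moments use the
#' population (divide-by-N) convention. Degenerate conventions: a constant
#' patch has skewness and kurtosis 0, entropy 0 and uniformity 1.
#'
#' @param patch numeric matrix (any size >= 2 x 2 accepted; 64 x 64 in the
#'   standard pipeline).
#' @param mm_per_px pixel spacing used for TotalEnergy (default 1, i.e.
#'   pixel units).
#' @param Ng number of bins for the entropy/uniformity histogram.
#' @return named numeric vector of length 19.
#' @export
first_order_features <- function(patch, mm_per_px = 1, Ng = 32L) {
  if (length(patch) == 0) stop_domain("empty patch")
  x <- as.numeric(patch)
  n <- length(x)
  mu <- mean(x)
  m2 <- mean((x - mu)^2)
  m3 <- mean((x - mu)^3)
  m4 <- mean((x - mu)^4)
  q <- stats::quantile(x, c(0.10, 0.25, 0.50, 0.75, 0.90), names = FALSE)
  mid <- x[x >= q[1] & x <= q[5]]
  p <- tabulate(quantize(patch, Ng = Ng)$levels, Ng) / n

  c(firstorder_Energy = sum(x^2),
    firstorder_TotalEnergy = sum(x^2) * mm_per_px^2,
    firstorder_Entropy = -sum(xlog2(p) * p),
    firstorder_Minimum = min(x),
    `firstorder_10Percentile` = q[1],
    `firstorder_90Percentile` = q[5],
    firstorder_Maximum = max(x),
    firstorder_Mean = mu,
    firstorder_Median = q[3],
    firstorder_InterquartileRange = q[4] - q[2],
    firstorder_Range = max(x) - min(x),
    firstorder_MeanAbsoluteDeviation = mean(abs(x - mu)),
    firstorder_RobustMeanAbsoluteDeviation = mean(abs(mid - mean(mid))),
    firstorder_RootMeanSquared = sqrt(mean(x^2)),
    firstorder_StandardDeviation = sqrt(m2),
    firstorder_Skewness = if (m2 > 0) m3 / m2^1.5 else 0,
    firstorder_Kurtosis = if (m2 > 0) m4 / m2^2 else 0,
    firstorder_Variance = m2,
    firstorder_Uniformity = sum(p^2))
}
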