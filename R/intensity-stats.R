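#' First-order statistical features of ROI intensities
#'
#' Computes the 17 statistical panel members over the raw (unfiltered) ROI
#' intensities. Definitions: `sd`/`variance` are sample (n-1) moments;
#' `mad` is the raw median absolute deviation (no normal-consistency
#' constant); `skewness` is Fisher's bias-uncorrected g1 and `kurtosis`
#' excess g2; `energy` is the unnormalised sum of squared intensities;
#' `entropy` (bits) and `uniformity` are taken over a 64 equal-width-bin
#' histogram spanning the ROI range; `p10`/`p90` are type-7 quantiles.
#' A constant ROI yields `skewness = kurtosis = 0`, `entropy = 0`,
#' `uniformity = 1`, keeping the feature vector finite.
#'
#' @param x numeric vector of ROI intensities (non-empty).
#' @param n_bins histogram bin count for entropy/uniformity (default 64).
#' @return named numeric vector of the 17 statistical features.
#' @export
statistical_features <- function(x, n_bins = 64L) {
  if (length(x) == 0L) stop("empty ROI: no intensities supplied")
  if (any(!is.finite(x))) stop("non-finite intensity in ROI")
  n <- length(x)
  mn <- min(x); mx <- max(x); mu <- mean(x)
  constant <- (mx == mn)
  m2 <- mean((x - mu)^2)
  skew <- if (constant || m2 == 0) 0 else mean((x - mu)^3) / m2^1.5
  kurt <- if (constant || m2 == 0) 0 else mean((x - mu)^4) / m2^2 - 3
  if (constant) {
    p <- 1  # single occupied bin
  } else {
    cuts <- seq(mn, mx, length.out = n_bins + 1L)
    b <- findInterval(x, cuts, rightmost.closed = TRUE)
    p <- tabulate(b, nbins = n_bins) / n
    p <- p[p > 0]
  }
  c(min = mn,
    max = mx,
    range = mx - mn,
    mean = mu,
    median = median(x),
    sd = if (n > 1) sd(x) else 0,
    variance = if (n > 1) var(x) else 0,
    mad = median(abs(x - median(x))),
    skewness = skew,
    kurtosis = kurt,
    energy = sum(x^2),
    entropy = -sum(p * log2(p)),
    uniformity = sum(p^2),
    rms = sqrt(mean(x^2)),
    iqr = IQR(x),
    p10 = unname(quantile(x, 0.10)),
    p90 = unname(quantile(x, 0.90)))
}
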