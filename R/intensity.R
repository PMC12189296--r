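#' @include utils.R
NULL

#' First-order histogram features of an intensity sample
#'
#' Computes the 12 histogram-family features from in-mask intensities
#' (pooled over slices by [extractPatientFeatures()]): mean, median,
#' maximum, minimum, range, population standard deviation
#' \eqn{\sqrt{\sum (f_i - \bar f)^2 / N}}, variance (its square), mean
#' absolute difference \eqn{\sum |f_i - \bar f| / N}, energy
#' \eqn{\sum f_i^2}, entropy \eqn{-\sum p_i \log_2 p_i} over a `bins`-bin
#' equal-width histogram of \[min, max\], skewness
#' \eqn{(\sum (f_i-\bar f)^3 / N) / sd^3} and kurtosis
#' \eqn{(\sum (f_i-\bar f)^4 / N) / sd^4} (non-excess: a normal sample
#' scores about 3). For a constant sample (sd = 0) skewness and kurtosis
#' are defined as 0 with a warning, and entropy is 0.
#'
#' @param values numeric vector of intensities, length >= 1, finite.
#' @param bins histogram bin count for the entropy (default 64).
#' @return named numeric(12) in canonical order
#'   (see `canonicalFeatureNames("hist")`).
#' @examples
#' histogramFeatures(c(1, 2, 3, 4))[c("hist_mean", "hist_mad", "hist_var")]
#' @export
histogramFeatures <- function(values, bins = 64L) {
  if (length(values) < 1L) stop("empty intensity sample", call. = FALSE)
  if (any(!is.finite(values))) stop("intensities must be finite", call. = FALSE)
  n <- length(values)
  m <- mean(values)
  sd0 <- sqrt(sum((values - m)^2) / n)
  mx <- max(values); mn <- min(values)

  if (sd0 == 0) {
    warning("constant intensity sample: skewness and kurtosis set to 0")
    skew <- 0; kurt <- 0; entro <- 0
  } else {
    skew <- (sum((values - m)^3) / n) / sd0^3
    kurt <- (sum((values - m)^4) / n) / sd0^4
    edges <- seq(mn, mx, length.out = bins + 1L)
    cnt <- tabulate(pmin(findInterval(values, edges, rightmost.closed = TRUE),
                         bins), nbins = bins)
    p <- cnt / n
    entro <- -sum(xlog2x(p))
  }

  c(hist_ener = sum(values^2),
    hist_entro = entro,
    hist_skew = skew,
    hist_kurt = kurt,
    hist_max = mx,
    hist_min = mn,
    hist_mean = m,
    hist_median = stats::median(values),
    hist_mad = sum(abs(values - m)) / n,
    hist_sd = sd0,
    hist_range = mx - mn,
    hist_var = sd0^2)
}
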