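# 12 time-domain features per channel per epoch.

TIME_FEATURE_NAMES <- c(
  "std", "mean", "p2p", "skewness", "kurtosis", "rms",
  "hjorth_mobility", "quantile", "hjorth_complexity", "variance",
  "decorr_time", "zero_crossings"
)

#' Hjorth parameters of a signal
#'
#' Activity is the signal variance \eqn{\sigma_x^2}; mobility is
#' \eqn{\sigma_d/\sigma_x} where \eqn{\sigma_d} is the standard deviation of
#' the first difference; complexity is \eqn{\sigma_{dd}/\sigma_d \cdot
#' \sigma_x/\sigma_d = \sigma_{dd}/\sigma_x} divided by mobility, i.e. the
#' mobility of the derivative over the mobility of the signal. Derivatives
#' are first differences.
#'
#' @param x Numeric vector, length >= 3.
#' @return Named numeric vector `(activity, mobility, complexity)`. A
#'   constant signal returns `(0, 0, 0)`.
#' @examples
#' hjorth(sin(2 * pi * 10 * (0:2499) / 250))
#' @export
hjorth <- function(x) {
  if (length(x) < 3L) stop("need at least 3 samples", call. = FALSE)
  sx <- sd(x)
  if (!is.finite(sx) || sx < .EPS) {
    return(c(activity = 0, mobility = 0, complexity = 0))
  }
  d <- diff(x)
  dd <- diff(d)
  sd1 <- sd(d)
  sd2 <- sd(dd)
  mob <- sd1 / sx
  cmplx <- if (sd1 < .EPS) 0 else (sd2 / sd1) / mob
  c(activity = sx^2, mobility = mob, complexity = cmplx)
}

# lag (samples) of first non-positive biased sample autocorrelation
decorrelation_time <- function(x) {
  n <- length(x)
  y <- x - mean(x)
  v <- sum(y^2)
  if (v < .EPS) return(0)
  # biased autocorrelation via FFT
  m <- nextn(2L * n)
  f <- fft(c(y, numeric(m - n)))
  ac <- Re(fft(f * Conj(f), inverse = TRUE))[seq_len(n)] / v / m
  idx <- which(ac <= 0)
  if (length(idx) == 0L) return(n - 1)
  idx[1] - 1L  # lags are 0-based
}

# sign changes of the mean-removed signal; exact zeros side with the
# positive half-plane, so a sine over k full periods counts 2k crossings
zero_crossings <- function(x) {
  s <- (x - mean(x)) >= 0
  n <- length(s)
  sum(s[-1] != s[-n])
}

#' Time-domain feature vector (12 features)
#'
#' Standard deviation, mean, peak-to-peak amplitude, skewness, excess
#' kurtosis, RMS, Hjorth mobility, 75th percentile, Hjorth complexity,
#' variance, decorrelation time (lag in samples of the first non-positive
#' autocorrelation) and number of zero crossings of the mean-removed signal.
#'
#' @param x Single-channel numeric series, length >= 3.
#' @param quantile_prob Probability of the quantile feature (default 0.75).
#' @return Named numeric vector of length 12.
#' @export
time_features <- function(x, quantile_prob = 0.75) {
  if (length(x) < 3L) stop("need at least 3 samples", call. = FALSE)
  n <- length(x)
  mu <- mean(x)
  v <- var(x)
  m2 <- mean((x - mu)^2)
  skw <- if (m2 < .EPS) 0 else mean((x - mu)^3) / m2^1.5
  kur <- if (m2 < .EPS) 0 else mean((x - mu)^4) / m2^2 - 3
  hj <- hjorth(x)
  out <- c(
    sqrt(v), mu, max(x) - min(x), skw, kur, sqrt(mean(x^2)),
    hj[["mobility"]], unname(quantile(x, quantile_prob)),
    hj[["complexity"]], v, decorrelation_time(x), zero_crossings(x)
  )
  names(out) <- TIME_FEATURE_NAMES
  out
}
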