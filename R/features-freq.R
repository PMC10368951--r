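# 48 frequency-domain features per channel per epoch.

RATIO_PAIRS <- list(
  c("delta", "theta"), c("delta", "alpha"), c("delta", "beta"),
  c("delta", "gamma"), c("theta", "alpha"), c("theta", "beta"),
  c("theta", "gamma"), c("alpha", "beta"), c("alpha", "gamma"),
  c("beta", "gamma")
)

FREQ_FEATURE_NAMES <- c(
  paste0("harm_", names(EEG_BANDS)),
  paste0("wav_energy_d", 1:6),
  "spec_hjorth_complexity",
  paste0("bp_", names(EEG_BANDS)),
  vapply(RATIO_PAIRS, function(p) paste0("ratio_", p[1], "_", p[2]), ""),
  "loglog_slope", "loglog_intercept", "loglog_r2", "loglog_rmse",
  "spec_hjorth_mobility", "sef95",
  paste0("benergy_", names(EEG_BANDS)),
  paste0("mf", 1:10)
)

#' Welch power spectral density
#'
#' Averaged modified periodogram (Hamming window, 50% overlap, per-segment
#' mean removal), one-sided density normalisation so that
#' `sum(power) * df` approximates the mean square of the signal.
#'
#' @param x Numeric vector, length >= 256.
#' @param fs Sampling rate in Hz.
#' @param nperseg Segment length in samples (default `fs`, i.e. 1 s).
#' @param overlap Fractional overlap between segments (default 0.5).
#' @return Object of class `attn_spectrum`: list with `freq` (Hz),
#'   `power` (density) and `df` (bin width, Hz).
#' @export
psd <- function(x, fs, nperseg = fs, overlap = 0.5) {
  n <- length(x)
  if (n < 256L) stop("need at least 256 samples for a PSD", call. = FALSE)
  nperseg <- min(as.integer(nperseg), n)
  step <- max(1L, as.integer(nperseg * (1 - overlap)))
  starts <- seq(1L, n - nperseg + 1L, by = step)
  w <- 0.54 - 0.46 * cos(2 * pi * seq(0, nperseg - 1) / (nperseg - 1))
  U <- sum(w^2)
  nf <- nperseg %/% 2L + 1L
  acc <- numeric(nf)
  for (s in starts) {
    seg <- x[s:(s + nperseg - 1L)]
    seg <- (seg - mean(seg)) * w
    acc <- acc + Mod(fft(seg)[seq_len(nf)])^2
  }
  pxx <- acc / (length(starts) * fs * U)
  # one-sided: double everything except DC (and Nyquist when nperseg even)
  dbl <- rep(2, nf)
  dbl[1] <- 1
  if (nperseg %% 2L == 0L) dbl[nf] <- 1
  pxx <- pxx * dbl
  structure(
    list(freq = (seq_len(nf) - 1) * fs / nperseg, power = pxx,
         df = fs / nperseg),
    class = "attn_spectrum"
  )
}

# half-open band selection [lo, hi); bands in a scheme then never
# double-count shared edges
.band_idx <- function(freq, band) which(freq >= band[1] & freq < band[2])

.band_power <- function(spec, band) {
  i <- .band_idx(spec$freq, band)
  if (length(i) == 0L) return(0)
  sum(spec$power[i]) * spec$df
}

#' Canonical band powers and their pairwise ratios
#'
#' Absolute power in the five canonical bands (delta, theta, alpha, beta,
#' gamma) followed by the ten pairwise ratios delta/theta, delta/alpha,
#' delta/beta, delta/gamma, theta/alpha, theta/beta, theta/gamma,
#' alpha/beta, alpha/gamma, beta/gamma.
#'
#' @param spec An `attn_spectrum` from [psd()].
#' @return Named numeric vector of length 15.
#' @export
band_powers_and_ratios <- function(spec) {
  bp <- vapply(EEG_BANDS, function(b) .band_power(spec, b), numeric(1))
  ratios <- vapply(RATIO_PAIRS, function(p) {
    bp[[p[1]]] / (bp[[p[2]]] + .EPS)
  }, numeric(1))
  out <- c(bp, ratios)
  names(out) <- FREQ_FEATURE_NAMES[13:27]
  out
}

#' Median frequency of ten sub-bands
#'
#' For each of the bands 0.5-2, 2-4, 4-5, 5-7, 7-10, 10-13, 13-15, 15-20,
#' 20-30 and 30-40 Hz, the frequency bin at which the cumulative within-band
#' power first reaches half the within-band total. A band with zero power
#' returns its midpoint.
#'
#' @inheritParams band_powers_and_ratios
#' @return Named numeric vector of length 10 (Hz).
#' @export
median_frequency <- function(spec) {
  out <- vapply(MF_BANDS, function(b) {
    i <- .band_idx(spec$freq, b)
    p <- spec$power[i]
    if (length(i) == 0L || sum(p) < .EPS) return(mean(b))
    cs <- cumsum(p)
    spec$freq[i[which(cs >= cs[length(cs)] / 2)[1]]]
  }, numeric(1))
  names(out) <- paste0("mf", 1:10)
  out
}

# brickwall FFT band-pass; band half-open [lo, hi)
fft_bandfilter <- function(x, fs, lo, hi) {
  n <- length(x)
  f <- (seq_len(n) - 1) * fs / n
  f <- pmin(f, fs - f)  # two-sided frequency axis
  keep <- f >= lo & f < hi
  Re(fft(fft(x) * keep, inverse = TRUE)) / n
}

#' Band energy of the raw signal
#'
#' Sum of squared samples of the band-filtered signal, per canonical band.
#'
#' @param x Numeric vector, length >= 256.
#' @param fs Sampling rate in Hz.
#' @return Named numeric vector of length 5.
#' @export
band_energy <- function(x, fs) {
  if (length(x) < 256L) stop("need at least 256 samples", call. = FALSE)
  out <- vapply(EEG_BANDS, function(b) {
    sum(fft_bandfilter(x, fs, b[1], b[2])^2)
  }, numeric(1))
  names(out) <- paste0("benergy_", names(EEG_BANDS))
  out
}

#' Miscellaneous spectral descriptors
#'
#' Harmonic parameters (spectral centroid of each canonical band), spectral
#' Hjorth mobility and complexity from spectral moments
#' \eqn{m_k = \sum f^k P(f) \Delta f} (mobility \eqn{\sqrt{m_2/m_0}},
#' complexity \eqn{\sqrt{m_4/m_2} / \sqrt{m_2/m_0}}), the log-log spectral
#' regression over 1-40 Hz (slope, intercept, R-squared, residual RMS) and
#' the 95% spectral edge frequency.
#'
#' @inheritParams band_powers_and_ratios
#' @return Named numeric vector of length 12.
#' @export
misc_spectral <- function(spec) {
  tot <- sum(spec$power) * spec$df
  harm <- vapply(EEG_BANDS, function(b) {
    i <- .band_idx(spec$freq, b)
    p <- spec$power[i]
    if (length(i) == 0L || sum(p) < .EPS) return(0)
    sum(spec$freq[i] * p) / sum(p)
  }, numeric(1))
  if (tot < .EPS) {
    mob <- 0; cmx <- 0; sef <- 0
    ll <- c(0, 0, 0, 0)
  } else {
    m0 <- tot
    m2 <- sum(spec$freq^2 * spec$power) * spec$df
    m4 <- sum(spec$freq^4 * spec$power) * spec$df
    mob <- sqrt(m2 / m0)
    cmx <- sqrt(m4 / m2) / mob
    cs <- cumsum(spec$power)
    sef <- spec$freq[which(cs >= 0.95 * cs[length(cs)])[1]]
    i <- which(spec$freq >= 1 & spec$freq <= 40 & spec$power > 0)
    if (length(i) >= 3L) {
      fit <- lm(log10(spec$power[i]) ~ log10(spec$freq[i]))
      res <- fit$residuals
      tss <- sum((log10(spec$power[i]) - mean(log10(spec$power[i])))^2)
      r2 <- if (tss < .EPS) 1 else 1 - sum(res^2) / tss
      ll <- c(coef(fit)[2], coef(fit)[1], r2, sqrt(mean(res^2)))
    } else {
      ll <- c(0, 0, 0, 0)
    }
  }
  out <- c(harm, cmx, ll, mob, sef)
  names(out) <- c(paste0("harm_", names(EEG_BANDS)),
                  "spec_hjorth_complexity",
                  "loglog_slope", "loglog_intercept", "loglog_r2",
                  "loglog_rmse", "spec_hjorth_mobility", "sef95")
  out
}

#' Frequency-domain feature vector (48 features)
#'
#' Aggregates, in fixed order: 5 harmonic parameters (per-band spectral
#' centroids), 6 wavelet detail-level energies (6-level Daubechies db4),
#' spectral Hjorth complexity, 15 band powers and ratios, 4 log-log
#' regression coefficients, spectral Hjorth mobility, 95% spectral edge
#' frequency, 5 band energies and 10 per-band median frequencies.
#'
#' @param x Single-channel numeric series (length >= 256).
#' @param fs Sampling rate in Hz.
#' @param wavelet Daubechies wavelet for the energy block (default "db4").
#' @return Named numeric vector of length 48.
#' @export
freq_features <- function(x, fs, wavelet = "db4") {
  spec <- psd(x, fs)
  ms <- misc_spectral(spec)
  out <- c(
    ms[paste0("harm_", names(EEG_BANDS))],
    dwt_energies(x, level = 6L, wavelet = wavelet),
    ms["spec_hjorth_complexity"],
    band_powers_and_ratios(spec),
    ms[c("loglog_slope", "loglog_intercept", "loglog_r2", "loglog_rmse")],
    ms["spec_hjorth_mobility"],
    ms["sef95"],
    band_energy(x, fs),
    median_frequency(spec)
  )
  names(out) <- FREQ_FEATURE_NAMES
  out
}
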