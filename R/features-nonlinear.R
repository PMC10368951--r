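# 63 non-linear-dynamics features per channel per epoch.

# coefficient-set tags for the 7 sets of a 6-level decomposition,
# coarse (approximation) to fine
.WSET_TAGS <- c("a6", paste0("d", 6:1))

NONLINEAR_FEATURE_NAMES <- c(
  "petrosian_fd", "line_length", "spectral_entropy", "hurst", "sampen",
  paste0("renyi", 1:10), paste0("tsallis", 1:10), paste0("shannon", 1:10),
  "apen", "svd_entropy", "perm_entropy", "higuchi_fd",
  paste0("went_", .WSET_TAGS),
  as.vector(rbind(paste0("tk_mean_", .WSET_TAGS),
                  paste0("tk_sd_", .WSET_TAGS))),
  "svd_fisher", "dfa", "katz_fd"
)

#' Teager-Kaiser energy operator
#'
#' \eqn{\psi(x[n]) = x^2[n] - x[n-1] x[n+1]}, evaluated at the interior
#' samples of the sequence.
#'
#' @param x Numeric vector, length >= 3.
#' @return Numeric vector of length `length(x) - 2`.
#' @export
teager_kaiser <- function(x) {
  n <- length(x)
  if (n < 3L) stop("need at least 3 samples", call. = FALSE)
  x[2:(n - 1)]^2 - x[1:(n - 2)] * x[3:n]
}

#' Teager-Kaiser energy features over wavelet coefficient sets (14 features)
#'
#' A 6-level Daubechies decomposition yields 7 coefficient sets (the
#' approximation plus 6 details). For each set, coarse to fine, the mean and
#' standard deviation of the Teager-Kaiser energy of the coefficient
#' sequence are reported: 2 x 7 = 14 features.
#'
#' @param x Numeric vector, length >= 64.
#' @param wavelet Daubechies wavelet (default "db4").
#' @return Named numeric vector of length 14, `(mean, sd)` per set.
#' @export
teager_kaiser_features <- function(x, wavelet = "db4") {
  co <- dwt_decompose(x, level = 6L, wavelet = wavelet)
  out <- numeric(0)
  for (k in seq_along(co)) {
    if (length(co[[k]]) < 3L) {
      stop("coefficient set ", names(co)[k], " has fewer than 3 values",
           call. = FALSE)
    }
    psi <- teager_kaiser(co[[k]])
    out <- c(out, mean(psi), sd(psi))
  }
  names(out) <- NONLINEAR_FEATURE_NAMES[47:60]
  out
}

#' Per-level wavelet entropy terms (7 features)
#'
#' Energies \eqn{E_j} of the 7 coefficient sets are normalised to
#' \eqn{p_j = E_j / E_t}; the 7 per-level terms \eqn{-p_j \ln p_j} are
#' returned (their sum is the total wavelet entropy, at most \eqn{\ln 7}).
#'
#' @inheritParams teager_kaiser_features
#' @return Named numeric vector of length 7, coarse to fine.
#' @export
wavelet_entropy <- function(x, wavelet = "db4") {
  co <- dwt_decompose(x, level = 6L, wavelet = wavelet)
  e <- vapply(co, function(ck) sum(ck^2), numeric(1))
  et <- sum(e)
  if (et < .EPS) stop("zero-energy signal", call. = FALSE)
  p <- e / et
  out <- ifelse(p > 0, -p * log(p), 0)
  names(out) <- NONLINEAR_FEATURE_NAMES[40:46]
  out
}

#' Spectral entropy families over ten sub-bands (10 features each)
#'
#' For each of the ten median-frequency sub-bands, the entropy of the
#' normalised within-band spectral distribution: Shannon
#' \eqn{-\sum p_i \ln p_i}, Renyi \eqn{(1-q)^{-1} \ln \sum p_i^q} or
#' Tsallis \eqn{(q-1)^{-1} (1 - \sum p_i^q)}.
#'
#' @param spec An `attn_spectrum` from [psd()].
#' @param kind One of `"shannon"`, `"renyi"`, `"tsallis"`.
#' @param q Entropy order for Renyi/Tsallis (default 2).
#' @return Named numeric vector of length 10; empty/zero-power bands give 0.
#' @export
entropy_family <- function(spec, kind = c("shannon", "renyi", "tsallis"),
                           q = 2) {
  kind <- match.arg(kind)
  out <- vapply(MF_BANDS, function(b) {
    i <- .band_idx(spec$freq, b)
    p <- spec$power[i]
    s <- sum(p)
    if (length(i) == 0L || s < .EPS) return(0)
    p <- p / s
    switch(kind,
      shannon = -sum(ifelse(p > 0, p * log(p), 0)),
      renyi = if (abs(q - 1) < 1e-9) {
        -sum(ifelse(p > 0, p * log(p), 0))
      } else {
        log(sum(p^q)) / (1 - q)
      },
      tsallis = if (abs(q - 1) < 1e-9) {
        -sum(ifelse(p > 0, p * log(p), 0))
      } else {
        (1 - sum(p^q)) / (q - 1)
      }
    )
  }, numeric(1))
  names(out) <- paste0(substr(kind, 1, nchar(kind)), 1:10)
  out
}

#' Sample and approximate entropy
#'
#' Template-matching regularity statistics with Chebyshev distance; sample
#' entropy excludes self-matches, approximate entropy includes them.
#'
#' @param x Numeric vector, length >= 100.
#' @param m Embedding dimension (default 2).
#' @param r Tolerance; default `0.2 * sd(x)`.
#' @return Named numeric vector `(sampen, apen)`. Constant input gives
#'   `(0, 0)`.
#' @export
regularity_entropies <- function(x, m = 2L, r = 0.2 * sd(x)) {
  if (length(x) < 100L) stop("need at least 100 samples", call. = FALSE)
  if (sd(x) < .EPS) return(c(sampen = 0, apen = 0))
  c(sampen = .sampen_cpp(x, as.integer(m), r),
    apen = .apen_cpp(x, as.integer(m), r))
}

.petrosian <- function(x) {
  n <- length(x)
  d <- diff(x)
  nd <- sum(diff(sign(d)[sign(d) != 0]) != 0)
  if (nd == 0) return(1)
  log10(n) / (log10(n) + log10(n / (n + 0.4 * nd)))
}

.katz <- function(x) {
  L <- sum(abs(diff(x)))
  d <- max(abs(x - x[1]))
  n <- length(x) - 1
  if (L < .EPS || d < .EPS) return(1)
  log10(n) / (log10(n) + log10(d / L))
}

#' Fractal dimensions (Petrosian, Higuchi, Katz)
#'
#' @param x Numeric vector, length >= 100.
#' @param kmax Maximum interval for the Higuchi estimator (default 10).
#' @return Named numeric vector `(petrosian, higuchi, katz)`; constant
#'   input gives all 1.
#' @export
fractal_dims <- function(x, kmax = 10L) {
  if (length(x) < 100L) stop("need at least 100 samples", call. = FALSE)
  if (sd(x) < .EPS) return(c(petrosian = 1, higuchi = 1, katz = 1))
  c(petrosian = .petrosian(x),
    higuchi = .higuchi_cpp(x, as.integer(kmax)),
    katz = .katz(x))
}

# delay-embedding matrix, dimension d, delay tau
.embed_matrix <- function(x, d, tau = 1L) {
  n <- length(x) - (d - 1L) * tau
  sapply(seq_len(d), function(j) x[(j - 1L) * tau + seq_len(n)])
}

#' Permutation entropy of ordinal patterns
#'
#' Shannon entropy of the distribution of ordinal patterns of `order`
#' consecutive samples, normalised by `log(order!)` so a monotone series
#' gives 0 and an equidistributed pattern set gives 1.
#'
#' @param x Numeric vector.
#' @param order Pattern length (default 3).
#' @param tau Delay between pattern samples (default 1).
#' @return Scalar in `[0, 1]`.
#' @export
permutation_entropy <- function(x, order = 3L, tau = 1L) {
  em <- .embed_matrix(x, order, tau)
  # code each row by pairwise "less than" comparisons (ties broken towards
  # the earlier sample, matching ranking with ties.method = "first")
  code <- integer(nrow(em))
  b <- 1L
  for (i in seq_len(order - 1L)) {
    for (j in (i + 1L):order) {
      code <- code + b * (em[, j] < em[, i])
      b <- 2L * b
    }
  }
  p <- tabulate(code + 1L, nbins = b)
  p <- p[p > 0] / length(code)
  h <- -sum(p * log(p))
  h / log(factorial(order))
}

.hurst_rs <- function(x) {
  n <- length(x)
  sizes <- unique(round(exp(seq(log(16), log(n %/% 2), length.out = 8))))
  rs <- vapply(sizes, function(w) {
    nseg <- n %/% w
    vals <- vapply(seq_len(nseg), function(k) {
      seg <- x[((k - 1) * w + 1):(k * w)]
      dev <- cumsum(seg - mean(seg))
      s <- sd(seg)
      if (s < .EPS) return(NA_real_)
      (max(dev) - min(dev)) / s
    }, numeric(1))
    mean(vals, na.rm = TRUE)
  }, numeric(1))
  ok <- is.finite(rs) & rs > 0
  if (sum(ok) < 3) return(0.5)
  unname(coef(lm(log(rs[ok]) ~ log(sizes[ok])))[2])
}

#' Detrended fluctuation analysis exponent
#'
#' Scaling exponent of the root-mean-square fluctuation of the integrated,
#' linearly detrended profile over log-spaced box sizes. White noise gives
#' 0.5, Brownian motion 1.5.
#'
#' @param x Numeric vector, length >= 256.
#' @param n_sizes Number of log-spaced box sizes between 16 and
#'   `length(x)/4` (default 16).
#' @return Scalar exponent.
#' @export
dfa_exponent <- function(x, n_sizes = 16L) {
  n <- length(x)
  if (n < 256L) stop("need at least 256 samples", call. = FALSE)
  if (sd(x) < .EPS) return(0)
  y <- cumsum(x - mean(x))
  sizes <- unique(round(exp(seq(log(16), log(n %/% 4), length.out = n_sizes))))
  fl <- vapply(sizes, function(w) {
    nseg <- n %/% w
    Y <- matrix(y[seq_len(nseg * w)], nrow = w)
    tc <- seq_len(w) - (w + 1) / 2
    b <- drop(crossprod(tc, Y)) / sum(tc^2)
    R <- Y - rep(colMeans(Y), each = w) - outer(tc, b)
    sqrt(mean(R^2))
  }, numeric(1))
  ok <- fl > 0
  unname(coef(lm(log(fl[ok]) ~ log(sizes[ok])))[2])
}

#' Assorted complexity measures
#'
#' Spectral entropy (Shannon entropy of the normalised full-band spectrum,
#' normalised by log of the number of bins), SVD entropy and SVD Fisher
#' information from the singular-value distribution of a delay-embedding
#' matrix, permutation entropy, rescaled-range Hurst exponent, DFA exponent
#' and line length \eqn{\sum |x[n+1] - x[n]|}.
#'
#' @param x Numeric vector, length >= 256.
#' @param fs Sampling rate in Hz.
#' @param svd_dim Embedding dimension for the SVD measures (default 10).
#' @return Named numeric vector of length 7.
#' @export
complexity_misc <- function(x, fs, svd_dim = 10L) {
  if (length(x) < 256L) stop("need at least 256 samples", call. = FALSE)
  if (sd(x) < .EPS) {
    return(c(spectral_entropy = 0, svd_entropy = 0, svd_fisher = 0,
             perm_entropy = 0, hurst = 0.5, dfa = 0, line_length = 0))
  }
  spec <- psd(x, fs)
  p <- spec$power / sum(spec$power)
  se <- -sum(ifelse(p > 0, p * log(p), 0)) / log(length(p))
  em <- .embed_matrix(x, svd_dim)
  sv <- sqrt(pmax(eigen(crossprod(em), symmetric = TRUE,
                        only.values = TRUE)$values, 0))
  ps <- sv / sum(sv)
  svde <- -sum(ifelse(ps > 0, ps * log(ps), 0))
  fisher <- sum(diff(ps)^2 / pmax(ps[-length(ps)], .EPS))
  c(spectral_entropy = se, svd_entropy = svde, svd_fisher = fisher,
    perm_entropy = permutation_entropy(x),
    hurst = .hurst_rs(x), dfa = dfa_exponent(x),
    line_length = sum(abs(diff(x))))
}

#' Non-linear dynamics feature vector (63 features)
#'
#' Aggregates, in fixed order: Petrosian fractal dimension, line length,
#' spectral entropy, Hurst exponent, sample entropy, 10 Renyi entropies,
#' 10 Tsallis entropies, 10 Shannon entropies (per spectral sub-band),
#' approximate entropy, SVD entropy, permutation entropy, Higuchi fractal
#' dimension, 7 wavelet-entropy terms, 14 Teager-Kaiser features, SVD
#' Fisher information, DFA exponent and Katz fractal dimension.
#'
#' @param x Single-channel numeric series (length >= 256).
#' @param fs Sampling rate in Hz.
#' @param wavelet Daubechies wavelet for the wavelet-based blocks.
#' @param q Order for the Renyi/Tsallis families (default 2).
#' @return Named numeric vector of length 63.
#' @export
nonlinear_features <- function(x, fs, wavelet = "db4", q = 2) {
  spec <- psd(x, fs)
  cm <- complexity_misc(x, fs)
  fd <- fractal_dims(x)
  re <- regularity_entropies(x)
  we <- tryCatch(wavelet_entropy(x, wavelet),
                 error = function(e) {
                   structure(numeric(7), names = NONLINEAR_FEATURE_NAMES[40:46])
                 })
  out <- c(
    fd[["petrosian"]], cm[["line_length"]], cm[["spectral_entropy"]],
    cm[["hurst"]], re[["sampen"]],
    entropy_family(spec, "renyi", q),
    entropy_family(spec, "tsallis", q),
    entropy_family(spec, "shannon"),
    re[["apen"]], cm[["svd_entropy"]], cm[["perm_entropy"]],
    fd[["higuchi"]],
    we,
    teager_kaiser_features(x, wavelet),
    cm[["svd_fisher"]], cm[["dfa"]], fd[["katz"]]
  )
  names(out) <- NONLINEAR_FEATURE_NAMES
  out
}
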