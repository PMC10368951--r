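# Group-level analyses: state-averaged feature t-tests, band-limited
# functional-connectivity contrasts with FDR correction, Z-scored
# band-power topographies, Morlet time-frequency maps.

#' State-averaged features per subject
#'
#' For every subject, feature column and state, the mean over that
#' subject's epochs of that state after a one-pass 3-SD outlier exclusion
#' (epoch values deviating more than `sd_limit` standard deviations from
#' the subject-state mean are dropped).
#'
#' @param designs List of `attn_design`, one per subject.
#' @param sd_limit Outlier criterion in standard deviations (default 3).
#' @return Array `subjects x features x states` with dimnames.
#' @export
subject_state_means <- function(designs, sd_limit = 3) {
  states <- c("attention", "non_attention")
  feats <- colnames(designs[[1]]$X)
  out <- array(NA_real_,
               dim = c(length(designs), length(feats), 2L),
               dimnames = list(names(designs), feats, states))
  for (i in seq_along(designs)) {
    d <- designs[[i]]
    for (s in states) {
      rows <- which(as.character(d$labels) == s)
      if (length(rows) == 0L) {
        stop("subject ", i, " has no epochs of state ", s, call. = FALSE)
      }
      sub <- d$X[rows, , drop = FALSE]
      mu <- colMeans(sub)
      sg <- apply(sub, 2, sd)
      for (j in seq_along(feats)) {
        keep <- if (sg[j] < .EPS) rep(TRUE, nrow(sub)) else
          abs(sub[, j] - mu[j]) <= sd_limit * sg[j]
        if (!any(keep)) {
          stop("all epochs excluded as outliers for feature ", feats[j],
               call. = FALSE)
        }
        out[i, j, s] <- mean(sub[keep, j])
      }
    }
  }
  out
}

#' Paired t-tests of state-averaged features
#'
#' Two-sided paired t-test across subjects (attention vs non-attention
#' state means) for every channel/feature pair.
#'
#' @param means Array from [subject_state_means()].
#' @return Matrix channels x features of p-values (zero-variance
#'   differences give p = 1).
#' @export
paired_feature_ttests <- function(means) {
  if (dim(means)[1] < 3L) stop("need at least 3 subjects", call. = FALSE)
  cols <- dimnames(means)[[2]]
  p <- vapply(seq_along(cols), function(j) {
    d <- means[, j, "attention"] - means[, j, "non_attention"]
    if (sd(d) < .EPS) return(1)
    t.test(d)$p.value
  }, numeric(1))
  ch <- sub(":.*$", "", cols)
  feat <- sub("^[^:]+:", "", cols)
  channels <- unique(ch)
  feats <- unique(feat)
  out <- matrix(NA_real_, length(channels), length(feats),
                dimnames = list(channels, feats))
  out[cbind(match(ch, channels), match(feat, feats))] <- p
  out
}

#' Band-limited functional connectivity of one subject
#'
#' Per epoch, Pearson correlation between band-filtered channel pairs;
#' correlation matrices are averaged within each state. Bands: delta,
#' theta, lower alpha (8-10 Hz), upper alpha (10-13 Hz), beta, gamma.
#'
#' @param es An `eeg_epochs` (one subject, >= 2 channels).
#' @param bands Named list of band edges (default `FC_BANDS`).
#' @return List per state (`attention`, `non_attention`) of lists per band
#'   of symmetric channel x channel correlation matrices with unit
#'   diagonal.
#' @export
connectivity_fc <- function(es, bands = FC_BANDS) {
  nch <- dim(es$data)[1]
  if (nch < 2L) stop("need at least 2 channels", call. = FALSE)
  n <- dim(es$data)[2]
  n_ep <- dim(es$data)[3]
  f <- (seq_len(n) - 1) * es$fs / n
  f <- pmin(f, es$fs - f)
  masks <- lapply(bands, function(b) f >= b[1] & f < b[2])
  acc <- list()
  cnt <- list()
  for (s in c("attention", "non_attention")) {
    acc[[s]] <- lapply(bands, function(b) matrix(0, nch, nch))
    cnt[[s]] <- 0L
  }
  for (k in seq_len(n_ep)) {
    s <- es$info$state[k]
    Fx <- mvfft(t(es$data[, , k]))
    for (b in names(bands)) {
      Y <- Re(mvfft(Fx * masks[[b]], inverse = TRUE)) / n
      cm <- suppressWarnings(cor(Y))
      cm[!is.finite(cm)] <- 0
      diag(cm) <- 1
      acc[[s]][[b]] <- acc[[s]][[b]] + cm
    }
    cnt[[s]] <- cnt[[s]] + 1L
  }
  out <- lapply(c(attention = "attention", non_attention = "non_attention"),
                function(s) {
    lapply(acc[[s]], function(m) {
      m <- m / max(cnt[[s]], 1L)
      dimnames(m) <- list(es$channel_names, es$channel_names)
      m
    })
  })
  out
}

#' Group contrast of functional connectivity with FDR correction
#'
#' Per band and edge (upper triangle), a two-sided paired t-test across
#' subjects of attention vs non-attention mean connectivity, followed by
#' Benjamini-Hochberg correction over the band's edges at level `q`.
#'
#' @param fc_att,fc_nonatt Lists (one element per subject) of per-band
#'   connectivity matrices, e.g. the `attention` / `non_attention` parts of
#'   [connectivity_fc()] applied per subject.
#' @param q FDR level (default 0.05).
#' @return List per band: `raw_p`, `adj_p` (matrices) and `mask` (logical,
#'   symmetric, diagonal `FALSE`).
#' @export
fc_group_test <- function(fc_att, fc_nonatt, q = 0.05) {
  ns <- length(fc_att)
  if (ns < 3L) stop("need at least 3 subjects", call. = FALSE)
  bands <- names(fc_att[[1]])
  nch <- nrow(fc_att[[1]][[1]])
  ut <- upper.tri(matrix(0, nch, nch))
  out <- lapply(bands, function(b) {
    da <- sapply(seq_len(ns), function(i) fc_att[[i]][[b]][ut])
    dn <- sapply(seq_len(ns), function(i) fc_nonatt[[i]][[b]][ut])
    d <- da - dn
    p <- apply(d, 1, function(v) {
      if (sd(v) < .EPS) 1 else t.test(v)$p.value
    })
    adj <- p.adjust(p, method = "BH")
    mk <- function(v) {
      m <- matrix(NA_real_, nch, nch,
                  dimnames = dimnames(fc_att[[1]][[b]]))
      m[ut] <- v
      m[lower.tri(m)] <- t(m)[lower.tri(m)]
      m
    }
    raw_m <- mk(p); adj_m <- mk(adj)
    mask <- adj_m < q
    diag(mask) <- FALSE
    diag(raw_m) <- 0; diag(adj_m) <- 0
    list(raw_p = raw_m, adj_p = adj_m, mask = mask)
  })
  names(out) <- bands
  out
}

#' Z-scored band-power topography
#'
#' Band powers are Z-scored per subject and band across all of that
#' subject's epochs and channels, then averaged per state across epochs and
#' subjects, giving a 5 bands x channels x 2 states table of normalised
#' power.
#'
#' @param designs List of `attn_design` containing the band-power columns
#'   (`CH:bp_<band>`).
#' @return Array `bands x channels x states`.
#' @export
band_topography <- function(designs) {
  bands <- names(EEG_BANDS)
  channels <- designs[[1]]$channels
  states <- c("attention", "non_attention")
  acc <- array(0, dim = c(length(bands), length(channels), 2L),
               dimnames = list(bands, channels, states))
  nsub <- length(designs)
  for (d in designs) {
    for (bi in seq_along(bands)) {
      cols <- paste0(channels, ":bp_", bands[bi])
      if (!all(cols %in% colnames(d$X))) {
        stop("band-power columns missing from design matrix", call. = FALSE)
      }
      v <- d$X[, cols, drop = FALSE]
      mu <- mean(v)
      sg <- sd(as.vector(v))
      z <- if (sg < .EPS) v * 0 else (v - mu) / sg
      for (s in states) {
        rows <- as.character(d$labels) == s
        acc[bi, , s] <- acc[bi, , s] + colMeans(z[rows, , drop = FALSE])
      }
    }
  }
  acc / nsub
}

#' Morlet time-frequency decomposition
#'
#' Convolution with complex Morlet wavelets (fixed number of cycles per
#' frequency); power is the squared magnitude of the analytic response.
#'
#' @param x Single-channel numeric series.
#' @param fs Sampling rate in Hz.
#' @param freqs Analysis frequencies in Hz, all within `(0, fs/2)`
#'   (default 1-50 Hz in 1 Hz steps).
#' @param n_cycles Wavelet width in cycles (default 7).
#' @return Object of class `attn_tfr`: list with `freqs`, `times` (s) and
#'   `power` (frequencies x time, non-negative).
#' @export
morlet_tfr <- function(x, fs, freqs = 1:50, n_cycles = 7) {
  if (any(freqs <= 0 | freqs >= fs / 2)) {
    stop("frequencies must lie in (0, fs/2)", call. = FALSE)
  }
  n <- length(x)
  m <- nextn(2L * n)
  fx <- fft(c(x, numeric(m - n)))
  power <- matrix(0, length(freqs), n)
  for (i in seq_along(freqs)) {
    f0 <- freqs[i]
    sig_t <- n_cycles / (2 * pi * f0)
    half <- ceiling(3.5 * sig_t * fs)
    tt <- (-half:half) / fs
    w <- exp(2i * pi * f0 * tt) * exp(-tt^2 / (2 * sig_t^2))
    w <- w / sqrt(sum(Mod(w)^2))
    fw <- fft(c(w, complex(real = numeric(m - length(w)))))
    conv <- fft(fx * fw, inverse = TRUE) / m
    # compensate the wavelet's group delay of `half` samples
    power[i, ] <- Mod(conv[half + seq_len(n)])^2
  }
  structure(list(freqs = freqs, times = (seq_len(n) - 1) / fs,
                 power = power),
            class = "attn_tfr")
}
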