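# Independent brute-force oracles used to pin down feature definitions.
# These are deliberately naive (loops, direct sums) and share no code with
# the package internals.

oracle_hjorth <- function(x) {
  sx <- sd(x)
  d1 <- x[-1] - x[-length(x)]
  d2 <- d1[-1] - d1[-length(d1)]
  mob <- sd(d1) / sx
  c(activity = sx^2, mobility = mob, complexity = (sd(d2) / sd(d1)) / mob)
}

oracle_sampen <- function(x, m, r) {
  n <- length(x); nm <- n - m; A <- 0; B <- 0
  for (i in 1:(nm - 1)) for (j in (i + 1):nm) {
    dm <- max(abs(x[i:(i + m - 1)] - x[j:(j + m - 1)]))
    if (dm <= r) {
      B <- B + 1
      if (max(dm, abs(x[i + m] - x[j + m])) <= r) A <- A + 1
    }
  }
  -log(A / B)
}

oracle_apen <- function(x, m, r) {
  n <- length(x)
  phi <- function(mm) {
    cnt <- n - mm + 1
    mean(sapply(1:cnt, function(i) {
      log(sum(sapply(1:cnt, function(j) {
        max(abs(x[i:(i + mm - 1)] - x[j:(j + mm - 1)])) <= r
      })) / cnt)
    }))
  }
  phi(m) - phi(m + 1)
}

# cumulative-sum median frequency over one band of a spectrum
oracle_band_mf <- function(spec, lo, hi) {
  i <- which(spec$freq >= lo & spec$freq < hi)
  tot <- sum(spec$power[i])
  cum <- 0
  for (k in i) {
    cum <- cum + spec$power[k]
    if (cum >= tot / 2) return(spec$freq[k])
  }
  NA_real_
}

# direct-summation spectral moment
oracle_moment <- function(spec, k) {
  s <- 0
  for (i in seq_along(spec$freq)) s <- s + spec$freq[i]^k * spec$power[i]
  s * spec$df
}

oracle_zero_crossings <- function(x) {
  y <- x - mean(x)
  cnt <- 0
  for (i in 2:length(y)) {
    if ((y[i] >= 0) != (y[i - 1] >= 0)) cnt <- cnt + 1
  }
  cnt
}

oracle_decorr <- function(x) {
  y <- x - mean(x); n <- length(y)
  denom <- sum(y^2)
  for (lag in 1:(n - 1)) {
    ac <- sum(y[1:(n - lag)] * y[(1 + lag):n]) / denom
    if (ac <= 0) return(lag)
  }
  n - 1
}

# a tiny recording with exactly placed annotations, for io tests
toy_recording <- function(n_trials = 2, task_s = 20, fs = 250,
                          channels = c("Fp1", "Fp2", "O1", "O2"),
                          seed = 1) {
  set.seed(seed)
  n_trial <- round((1 + task_s + 2) * fs)
  n <- n_trials * n_trial
  sig <- matrix(rnorm(length(channels) * n, sd = 10), length(channels), n)
  onsets <- (seq_len(n_trials) - 1) * n_trial + fs
  ann <- data.frame(onset = onsets, duration = task_s * fs,
                    state = rep(c("attention", "non_attention"),
                                length.out = n_trials))
  as_recording(sig, fs = fs, channel_names = channels, annotations = ann,
               subject_id = "T01")
}

# quick small-session epochs for feature/classify tests
quick_epochs <- function(n_trials = 4, seed = 1, task_s = 20,
                         channels = c("Fp1", "Fp2", "O1", "O2"),
                         effect = effect_spec(band_gain = c(alpha = 1),
                                              affected_channels = channels)) {
  par <- paradigm_spec(n_trials = n_trials, cue_s = 1, task_s = task_s,
                       rest_s = 2, channels = channels)
  rec <- generate_subject(par, effect, seed = seed)
  segment_epochs(rec, epoch_s = 10, epochs_per_trial = floor(task_s / 10))
}
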