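# Paradigm-faithful synthetic EEG: cohorts of sessions with a controllable
# attention effect, so the whole pipeline is testable without recordings.

#' Paradigm specification
#'
#' Trial structure of a recording session: each trial is a cue, a task
#' period (the only part that is epoched downstream) and a rest period.
#' States are balanced: exactly half the trials are attention trials, in
#' randomised order.
#'
#' @param n_trials Number of trials (even; default 20).
#' @param cue_s,task_s,rest_s Segment durations in seconds (defaults 3, 60,
#'   10).
#' @param fs Sampling rate in Hz (default 250).
#' @param channels Ordered channel labels (default: the standard 30-channel
#'   montage in `EEG_CHANNELS`).
#' @return Object of class `paradigm_spec`.
#' @export
paradigm_spec <- function(n_trials = 20L, cue_s = 3, task_s = 60,
                          rest_s = 10, fs = 250,
                          channels = EEG_CHANNELS) {
  if (n_trials < 2L || n_trials %% 2L != 0L) {
    stop("n_trials must be even and >= 2 (balanced states)", call. = FALSE)
  }
  if (any(c(cue_s, task_s, rest_s) <= 0) || fs <= 0) {
    stop("all durations and fs must be positive", call. = FALSE)
  }
  if (length(channels) == 0L || anyDuplicated(channels)) {
    stop("channels must be a non-empty list of unique labels", call. = FALSE)
  }
  structure(
    list(n_trials = as.integer(n_trials), cue_s = cue_s, task_s = task_s,
         rest_s = rest_s, fs = fs, channels = channels),
    class = "paradigm_spec"
  )
}

#' Attention-effect specification
#'
#' The attention state is emulated as a multiplicative reduction of band
#' power during task segments on a subset of channels (prefrontal and
#' occipital by default, where the attention-related power decrease is
#' expressed). The background is 1/f-shaped band-limited Gaussian noise with
#' a shared across-channel component plus white sensor noise; optional
#' high-amplitude transients emulate movement artifacts.
#'
#' @param band_gain Named multiplicative power factors applied during
#'   attention task segments; names from
#'   `c("delta","theta","alpha","beta","gamma")`. Defaults: theta, alpha and
#'   beta at 0.7 (attention lower than non-attention); unnamed bands 1.
#' @param affected_channels Channels carrying the effect (default prefrontal
#'   Fp1/Fp2/F7/F3/Fz/F4/F8 and occipital O1/Oz/O2).
#' @param noise_exponent Spectral slope of the 1/f background (default 1).
#' @param artifact_rate Expected artifacts per minute (default 0).
#' @param subject_gain_sd Inter-subject dispersion of log band gains
#'   (default 0.1).
#' @param shared_frac Amplitude fraction of the common across-channel
#'   background component (default 0.3).
#' @return Object of class `effect_spec`.
#' @export
effect_spec <- function(band_gain = c(theta = 0.7, alpha = 0.7, beta = 0.7),
                        affected_channels = c("Fp1", "Fp2", "F7", "F3",
                                              "Fz", "F4", "F8",
                                              "O1", "Oz", "O2"),
                        noise_exponent = 1, artifact_rate = 0,
                        subject_gain_sd = 0.1, shared_frac = 0.3) {
  gains <- structure(rep(1, length(EEG_BANDS)), names = names(EEG_BANDS))
  if (length(band_gain)) {
    bad <- setdiff(names(band_gain), names(EEG_BANDS))
    if (length(bad)) stop("unknown band(s): ", paste(bad, collapse = ", "),
                          call. = FALSE)
    gains[names(band_gain)] <- band_gain
  }
  if (any(gains <= 0)) stop("band gains must be positive", call. = FALSE)
  if (shared_frac < 0 || shared_frac >= 1) {
    stop("shared_frac must be in [0, 1)", call. = FALSE)
  }
  structure(
    list(band_gain = gains, affected_channels = affected_channels,
         noise_exponent = noise_exponent, artifact_rate = artifact_rate,
         subject_gain_sd = subject_gain_sd, shared_frac = shared_frac),
    class = "effect_spec"
  )
}

# two-sided 1/f^(chi/2) amplitude envelope on the FFT grid of length n,
# normalised to unit mean square (so unit-variance white input stays
# unit-variance), zero at DC
.noise_envelope <- function(n, fs, chi) {
  f <- (seq_len(n) - 1) * fs / n
  f <- pmin(f, fs - f)
  amp <- pmax(f, 0.5)^(-chi / 2)
  amp[1] <- 0
  amp / sqrt(mean(amp^2))
}

# per-bin sqrt power gain from per-band gains (length-5 named vector)
.gain_curve <- function(n, fs, gains) {
  f <- (seq_len(n) - 1) * fs / n
  f <- pmin(f, fs - f)
  g <- rep(1, n)
  for (b in names(EEG_BANDS)) {
    rng <- EEG_BANDS[[b]]
    g[f >= rng[1] & f < rng[2]] <- gains[[b]]
  }
  sqrt(g)
}

# one segment for all channels: colored Gaussian noise, per-channel band
# gains (columns of gain_mx are channels), shared component, sensor noise
.gen_segment <- function(n, nch, fs, chi, gain_mx, shared_frac,
                         rms = 10, sensor_sd = 1) {
  env <- .noise_envelope(n, fs, chi)
  w <- matrix(rnorm(n * nch), n, nch)
  fw <- mvfft(w) * env
  own <- Re(mvfft(fw * gain_mx, inverse = TRUE)) / n
  common <- Re(fft(fft(rnorm(n)) * env, inverse = TRUE)) / n
  sig <- sqrt(1 - shared_frac^2) * own + shared_frac * common
  rms * sig + matrix(rnorm(n * nch, sd = sensor_sd), n, nch)
}

#' Generate one synthetic recording session
#'
#' Builds a full session (`n_trials` trials of cue + task + rest) of
#' 1/f-background EEG in microvolts (background RMS about 10 uV). During
#' the task segment of attention trials, band powers on the affected
#' channels are scaled by `band_gain`. Annotations mark task-segment onsets
#' (0-based samples), durations and states.
#'
#' @param paradigm A [paradigm_spec()].
#' @param effect An [effect_spec()].
#' @param seed Integer seed; the session is deterministic given the seed.
#' @param subject_id Label stored with the recording (default "S01").
#' @return Object of class `eeg_recording` (see [as_recording()]) with
#'   attributes `ground_truth` (per-trial states) and `seed`.
#' @examples
#' rec <- generate_subject(paradigm_spec(n_trials = 2, task_s = 12),
#'                         effect_spec(), seed = 7)
#' dim(rec$signal)
#' @export
generate_subject <- function(paradigm, effect, seed, subject_id = "S01") {
  stopifnot(inherits(paradigm, "paradigm_spec"), inherits(effect, "effect_spec"))
  set.seed(seed)
  fs <- paradigm$fs
  ch <- paradigm$channels
  nch <- length(ch)
  n_cue <- round(paradigm$cue_s * fs)
  n_task <- round(paradigm$task_s * fs)
  n_rest <- round(paradigm$rest_s * fs)
  n_trial <- n_cue + n_task + n_rest
  nt <- paradigm$n_trials

  states <- sample(rep(c("attention", "non_attention"), each = nt %/% 2L))

  neutral <- matrix(1, 1, nch)
  att_gain_bins <- function(n) {
    g <- matrix(1, n, nch)
    idx <- ch %in% effect$affected_channels
    if (any(idx)) {
      g[, idx] <- .gain_curve(n, fs, effect$band_gain)
    }
    g
  }

  sig <- matrix(0, nrow = nt * n_trial, ncol = nch)
  onsets <- integer(nt)
  for (t in seq_len(nt)) {
    off <- (t - 1L) * n_trial
    gmx <- if (states[t] == "attention") att_gain_bins(n_task) else
      matrix(1, n_task, nch)
    sig[off + seq_len(n_cue), ] <-
      .gen_segment(n_cue, nch, fs, effect$noise_exponent,
                   matrix(1, n_cue, nch), effect$shared_frac)
    sig[off + n_cue + seq_len(n_task), ] <-
      .gen_segment(n_task, nch, fs, effect$noise_exponent, gmx,
                   effect$shared_frac)
    sig[off + n_cue + n_task + seq_len(n_rest), ] <-
      .gen_segment(n_rest, nch, fs, effect$noise_exponent,
                   matrix(1, n_rest, nch), effect$shared_frac)
    onsets[t] <- off + n_cue
  }

  # artifact transients: half-second 300-500 uV half-sines on random channels
  if (effect$artifact_rate > 0) {
    minutes <- nrow(sig) / fs / 60
    n_art <- stats::rpois(1, effect$artifact_rate * minutes)
    wlen <- round(0.5 * fs)
    shape <- sin(pi * seq_len(wlen) / wlen)
    for (a in seq_len(n_art)) {
      pos <- sample.int(nrow(sig) - wlen, 1)
      chan <- sample.int(nch, 1)
      amp <- runif(1, 300, 500) * sample(c(-1, 1), 1)
      sig[pos + seq_len(wlen), chan] <-
        sig[pos + seq_len(wlen), chan] + amp * shape
    }
  }

  ann <- data.frame(onset = onsets, duration = n_task, state = states,
                    stringsAsFactors = FALSE)
  rec <- as_recording(t(sig), fs = fs, channel_names = ch,
                      annotations = ann, subject_id = subject_id)
  attr(rec, "ground_truth") <- states
  attr(rec, "seed") <- seed
  rec
}

#' Generate a synthetic cohort
#'
#' Each subject gets a reproducible seed derived from the master seed and
#' its own band gains drawn on the log scale with dispersion
#' `subject_gain_sd`, emulating inter-subject variability of the effect.
#'
#' @param n_subjects Number of subjects (>= 2).
#' @inheritParams generate_subject
#' @return List of `eeg_recording` objects, named by subject id.
#' @export
generate_cohort <- function(n_subjects, paradigm, effect, seed) {
  if (n_subjects < 2L) {
    stop("a cohort needs at least 2 subjects", call. = FALSE)
  }
  set.seed(seed)
  sub_seeds <- sample.int(.Machine$integer.max - 1L, n_subjects)
  log_shift <- matrix(rnorm(n_subjects * length(EEG_BANDS),
                            sd = effect$subject_gain_sd),
                      n_subjects, length(EEG_BANDS))
  ids <- sprintf("S%02d", seq_len(n_subjects))
  out <- lapply(seq_len(n_subjects), function(i) {
    eff_i <- effect
    eff_i$band_gain <- exp(log(effect$band_gain) + log_shift[i, ])
    # bands with no planted effect stay exactly neutral
    eff_i$band_gain[effect$band_gain == 1] <- 1
    generate_subject(paradigm, eff_i, seed = sub_seeds[i],
                     subject_id = ids[i])
  })
  names(out) <- ids
  out
}
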