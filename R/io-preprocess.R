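# Recording container, file round-trip (array container / EDF),
# band-pass filtering, epoch segmentation, artifact rejection.

#' Construct a recording
#'
#' @param signal Channels x samples numeric matrix, amplitudes in
#'   microvolts.
#' @param fs Sampling rate in Hz.
#' @param channel_names Ordered unique channel labels, one per row.
#' @param annotations Data frame with columns `onset` (0-based sample),
#'   `duration` (samples) and `state`; every annotation must lie within the
#'   signal.
#' @param subject_id Optional subject label.
#' @return Object of class `eeg_recording`.
#' @export
as_recording <- function(signal, fs, channel_names,
                         annotations = NULL, subject_id = NA_character_) {
  signal <- as.matrix(signal)
  if (fs <= 0) stop("fs must be positive", call. = FALSE)
  if (nrow(signal) != length(channel_names)) {
    stop("channel count mismatch: ", nrow(signal), " rows vs ",
         length(channel_names), " names", call. = FALSE)
  }
  if (anyDuplicated(channel_names)) {
    stop("channel names must be unique", call. = FALSE)
  }
  if (!is.null(annotations)) {
    stopifnot(all(c("onset", "duration", "state") %in% names(annotations)))
    if (any(annotations$onset < 0) ||
        any(annotations$onset + annotations$duration > ncol(signal))) {
      stop("annotation outside signal bounds", call. = FALSE)
    }
  }
  rownames(signal) <- channel_names
  structure(
    list(signal = signal, fs = fs, channel_names = channel_names,
         annotations = annotations, subject_id = subject_id),
    class = "eeg_recording"
  )
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$signal), ncol(x$signal), x$fs, ncol(x$signal) / x$fs))
  if (!is.null(x$annotations)) {
    cat(sprintf("  %d annotated segments (%s)\n", nrow(x$annotations),
                paste(names(table(x$annotations$state)), collapse = ", ")))
  }
  invisible(x)
}

.sidecar <- function(path) paste0(path, ".json")

#' Write a recording to disk
#'
#' Two containers are supported. `"array"`: raw little-endian float64
#' samples (channel-major) plus a JSON sidecar holding `fs`,
#' `channel_names`, `n_samples`, `subject_id` and the annotations.
#' `"edf"`: a minimal 16-bit EDF file (one 1-s data record per second);
#' annotations travel in the same JSON sidecar since plain EDF has no
#' annotation channel.
#'
#' @param rec An `eeg_recording`.
#' @param path Output file path.
#' @param format `"array"` or `"edf"` (default from the file extension,
#'   falling back to `"array"`).
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path, format = NULL) {
  if (is.null(format)) {
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf" else "array"
  }
  meta <- list(fs = rec$fs, channel_names = rec$channel_names,
               n_samples = ncol(rec$signal), subject_id = rec$subject_id,
               annotations = rec$annotations)
  jsonlite::write_json(meta, .sidecar(path), auto_unbox = TRUE, digits = NA,
                       null = "null")
  if (format == "array") {
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(as.vector(t(rec$signal)), con, size = 8, endian = "little")
  } else if (format == "edf") {
    .write_edf(rec, path)
  } else {
    stop("unknown format: ", format, call. = FALSE)
  }
  invisible(path)
}

#' Read a recording from disk
#'
#' Counterpart of [write_recording()]. The JSON sidecar written next to the
#' file is required (it carries sampling rate, channel names and
#' annotations for the array container, and annotations for EDF).
#'
#' @param path File path.
#' @param format `"array"` or `"edf"`; inferred from the extension when
#'   `NULL`.
#' @return An `eeg_recording`.
#' @export
read_recording <- function(path, format = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (is.null(format)) {
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf" else "array"
  }
  sc <- .sidecar(path)
  if (!file.exists(sc)) {
    stop("missing annotation sidecar: ", sc, call. = FALSE)
  }
  meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
  ann <- meta$annotations
  if (!is.null(ann) && length(ann)) ann <- as.data.frame(ann)
  if (format == "array") {
    nch <- length(meta$channel_names)
    con <- file(path, "rb")
    on.exit(close(con))
    vals <- readBin(con, numeric(), n = nch * meta$n_samples, size = 8,
                    endian = "little")
    sig <- t(matrix(vals, nrow = meta$n_samples, ncol = nch))
  } else if (format == "edf") {
    edf <- .read_edf(path)
    if (length(edf$channel_names) != length(meta$channel_names)) {
      stop("channel count mismatch between EDF and sidecar", call. = FALSE)
    }
    sig <- edf$signal
    meta$channel_names <- edf$channel_names
    meta$fs <- edf$fs
  } else {
    stop("unknown format: ", format, call. = FALSE)
  }
  as_recording(sig, fs = meta$fs, channel_names = meta$channel_names,
               annotations = ann,
               subject_id = if (is.null(meta$subject_id)) NA else
                 meta$subject_id)
}

# --- minimal EDF (16-bit) ---------------------------------------------------

.pad <- function(s, n) formatC(substr(s, 1, n), width = n, flag = "-")

.write_edf <- function(rec, path) {
  ns <- nrow(rec$signal)
  fs <- rec$fs
  n_rec <- ceiling(ncol(rec$signal) / fs)
  n_samp <- n_rec * fs
  sig <- cbind(rec$signal,
               matrix(0, ns, n_samp - ncol(rec$signal)))
  pmin_ <- apply(sig, 1, min)
  pmax_ <- apply(sig, 1, max)
  pmax_ <- pmax(pmax_, pmin_ + 1e-6)
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    .pad("0", 8), .pad("X", 80), .pad("X", 80),
    .pad("01.01.00", 8), .pad("00.00.00", 8),
    .pad(as.character(256 * (ns + 1)), 8), .pad("", 44),
    .pad(as.character(n_rec), 8), .pad("1", 8), .pad(as.character(ns), 4)
  )
  writeChar(hdr, con, eos = NULL)
  fld <- function(vals, w) {
    writeChar(paste(vapply(vals, .pad, "", n = w), collapse = ""), con,
              eos = NULL)
  }
  fld(rec$channel_names, 16)
  fld(rep("", ns), 80)                 # transducer
  fld(rep("uV", ns), 8)                # physical dimension
  fld(formatC(pmin_, format = "g", digits = 7), 8)
  fld(formatC(pmax_, format = "g", digits = 7), 8)
  fld(rep("-32768", ns), 8)
  fld(rep("32767", ns), 8)
  fld(rep("", ns), 80)                 # prefiltering
  fld(rep(as.character(fs), ns), 8)    # samples per record
  fld(rep("", ns), 32)                 # reserved
  scale <- (pmax_ - pmin_) / 65535
  for (r in seq_len(n_rec)) {
    idx <- (r - 1) * fs + seq_len(fs)
    for (c in seq_len(ns)) {
      dig <- round((sig[c, idx] - pmin_[c]) / scale[c]) - 32768
      writeBin(as.integer(pmin(pmax(dig, -32768), 32767)), con, size = 2,
               endian = "little")
    }
  }
  invisible(path)
}

.read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  readChar(con, 252, useBytes = TRUE)
  ns <- as.integer(readChar(con, 4, useBytes = TRUE))
  labels <- trimws(vapply(seq_len(ns), function(i)
    readChar(con, 16, useBytes = TRUE), ""))
  readChar(con, ns * 80, useBytes = TRUE)
  readChar(con, ns * 8, useBytes = TRUE)
  pmin_ <- as.numeric(vapply(seq_len(ns), function(i)
    readChar(con, 8, useBytes = TRUE), ""))
  pmax_ <- as.numeric(vapply(seq_len(ns), function(i)
    readChar(con, 8, useBytes = TRUE), ""))
  dmin <- as.numeric(vapply(seq_len(ns), function(i)
    readChar(con, 8, useBytes = TRUE), ""))
  dmax <- as.numeric(vapply(seq_len(ns), function(i)
    readChar(con, 8, useBytes = TRUE), ""))
  readChar(con, ns * 80, useBytes = TRUE)
  spr <- as.integer(vapply(seq_len(ns), function(i)
    readChar(con, 8, useBytes = TRUE), ""))
  readChar(con, ns * 32, useBytes = TRUE)
  # re-read record count from the fixed header
  seek(con, 236)
  n_rec <- as.integer(readChar(con, 8, useBytes = TRUE))
  dur <- as.numeric(readChar(con, 8, useBytes = TRUE))
  seek(con, 256 * (ns + 1))
  fs <- spr[1] / dur
  sig <- matrix(0, ns, n_rec * spr[1])
  scale <- (pmax_ - pmin_) / (dmax - dmin)
  for (r in seq_len(n_rec)) {
    for (c in seq_len(ns)) {
      dig <- readBin(con, integer(), n = spr[c], size = 2, signed = TRUE,
                     endian = "little")
      sig[c, (r - 1) * spr[c] + seq_len(spr[c])] <-
        (dig - dmin[c]) * scale[c] + pmin_[c]
    }
  }
  list(signal = sig, channel_names = labels, fs = fs)
}

# --- filtering --------------------------------------------------------------

#' Zero-phase FIR band-pass filter
#'
#' Hamming windowed-sinc FIR design (order sized for a transition width of
#' at most the low cut-off, so the default 0.5 Hz edge is sharp), applied
#' zero-phase as the squared magnitude response in the frequency domain
#' with reflective padding -- the forward-backward application of the same
#' FIR. Annotations are untouched.
#'
#' @param rec An `eeg_recording`.
#' @param low,high Band edges in Hz (defaults 0.5 and 50).
#' @param order Filter order; default `ceiling(3.3 * fs / low)` rounded up
#'   to even.
#' @return Filtered `eeg_recording` of the same shape.
#' @export
bandpass_fir <- function(rec, low = 0.5, high = 50, order = NULL) {
  fs <- rec$fs
  if (!(low > 0 && low < high && high < fs / 2)) {
    stop("band edges must satisfy 0 < low < high < fs/2", call. = FALSE)
  }
  if (is.null(order)) order <- 2 * ceiling(3.3 * fs / low / 2)
  b <- signal::fir1(order, c(low, high) / (fs / 2), type = "pass")
  n <- ncol(rec$signal)
  pad <- min(order, n - 1)
  m <- n + 2 * pad
  H2 <- Mod(fft(c(b, rep(0, m - length(b)))))^2
  out <- rec
  for (c in seq_len(nrow(rec$signal))) {
    x <- rec$signal[c, ]
    xp <- c(rev(x[seq_len(pad) + 1]), x, rev(x[n - seq_len(pad)]))
    y <- Re(fft(fft(xp) * H2, inverse = TRUE)) / m
    out$signal[c, ] <- y[pad + seq_len(n)]
  }
  out
}

# --- epoching ---------------------------------------------------------------

#' Cut annotated task segments into fixed-length epochs
#'
#' Each annotated task segment is cut into `epochs_per_trial` contiguous
#' non-overlapping epochs of `epoch_s` seconds (defaults: 6 epochs of 10 s,
#' i.e. 2,500 samples at 250 Hz, from a 15,000-sample task segment). Epochs
#' inherit the trial's state label; ordering is chronological (trial, then
#' epoch index).
#'
#' @param rec An `eeg_recording` with task annotations.
#' @param epoch_s Epoch length in seconds (default 10).
#' @param epochs_per_trial Epochs cut per trial (default 6).
#' @return Object of class `eeg_epochs`: list with `data` (channels x
#'   samples x epochs array), `info` (trial, epoch index, state, subject),
#'   `fs`, `channel_names` and an empty `rejection_log`.
#' @export
segment_epochs <- function(rec, epoch_s = 10, epochs_per_trial = 6L) {
  ann <- rec$annotations
  if (is.null(ann) || nrow(ann) == 0L) {
    stop("recording has no annotations", call. = FALSE)
  }
  len <- round(epoch_s * rec$fs)
  need <- len * epochs_per_trial
  short <- which(ann$duration < need)
  if (length(short)) {
    stop("task segment of trial ", short[1], " has ", ann$duration[short[1]],
         " samples; need ", need, call. = FALSE)
  }
  n_ep <- nrow(ann) * epochs_per_trial
  data <- array(NA_real_, dim = c(nrow(rec$signal), len, n_ep),
                dimnames = list(rec$channel_names, NULL, NULL))
  info <- data.frame(trial = integer(n_ep), epoch = integer(n_ep),
                     state = character(n_ep), stringsAsFactors = FALSE)
  k <- 0L
  for (t in seq_len(nrow(ann))) {
    for (e in seq_len(epochs_per_trial) - 1L) {
      k <- k + 1L
      start <- ann$onset[t] + e * len  # 0-based onset
      data[, , k] <- rec$signal[, start + seq_len(len), drop = FALSE]
      info$trial[k] <- t
      info$epoch[k] <- e
      info$state[k] <- ann$state[t]
    }
  }
  info$subject_id <- rec$subject_id
  structure(
    list(data = data, info = info, fs = rec$fs,
         channel_names = rec$channel_names,
         rejection_log = data.frame(trial = integer(), epoch = integer(),
                                    reason = character())),
    class = "eeg_epochs"
  )
}

#' @export
print.eeg_epochs <- function(x, ...) {
  cat(sprintf("<eeg_epochs> %d epochs x %d channels x %d samples @ %g Hz\n",
              dim(x$data)[3], dim(x$data)[1], dim(x$data)[2], x$fs))
  print(table(x$info$state))
  if (nrow(x$rejection_log)) {
    cat(sprintf("  %d epochs rejected\n", nrow(x$rejection_log)))
  }
  invisible(x)
}

#' Reject artifact epochs
#'
#' Drops epochs whose peak absolute amplitude on any channel exceeds
#' `amp_threshold` (default 100 uV, standard practice for scalp EEG).
#' Optionally also flags myogenic contamination as epochs whose 30-50 Hz
#' power z-score across epochs exceeds `myo_z` (off by default). Survivors
#' keep chronological order; removals are logged. Idempotent.
#'
#' @param es An `eeg_epochs`.
#' @param amp_threshold Peak-amplitude criterion in microvolts.
#' @param myo_z High-frequency power z-score criterion, or `NULL` to
#'   disable (default).
#' @return Filtered `eeg_epochs` with an updated `rejection_log`.
#' @export
reject_artifacts <- function(es, amp_threshold = 100, myo_z = NULL) {
  if (amp_threshold <= 0) stop("threshold must be positive", call. = FALSE)
  n <- dim(es$data)[3]
  peak <- vapply(seq_len(n), function(k) max(abs(es$data[, , k])), numeric(1))
  drop <- peak > amp_threshold
  reason <- ifelse(drop, "amplitude", NA_character_)
  if (!is.null(myo_z)) {
    hf <- vapply(seq_len(n), function(k) {
      mean(apply(es$data[, , k, drop = FALSE][, , 1], 1, function(x)
        sum(fft_bandfilter(x, es$fs, 30, 50)^2)))
    }, numeric(1))
    z <- (hf - mean(hf)) / (sd(hf) + .EPS)
    myo <- z > myo_z & !drop
    drop <- drop | myo
    reason[myo] <- "myoelectric"
  }
  if (all(drop)) {
    stop("all epochs rejected; review the amplitude threshold (",
         amp_threshold, " uV)", call. = FALSE)
  }
  log_new <- data.frame(trial = es$info$trial[drop],
                        epoch = es$info$epoch[drop],
                        reason = reason[drop], stringsAsFactors = FALSE)
  out <- es
  out$data <- es$data[, , !drop, drop = FALSE]
  out$info <- es$info[!drop, , drop = FALSE]
  rownames(out$info) <- NULL
  out$rejection_log <- rbind(es$rejection_log, log_new)
  out
}
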