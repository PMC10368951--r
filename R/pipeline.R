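# Configuration and the end-to-end workflow:
# simulate -> preprocess -> extract -> classify -> group stats.

.CFG_DEFAULTS <- list(
  n_subjects = 3L, n_trials = 20L, cue_s = 3, task_s = 60, rest_s = 10,
  fs = 250, channels = NULL,            # NULL = full 30-channel montage
  band_gain = list(theta = 0.7, alpha = 0.7, beta = 0.7),
  affected_channels = c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8",
                        "O1", "Oz", "O2"),
  noise_exponent = 1, artifact_rate = 0, subject_gain_sd = 0.1,
  filter_low = 0.5, filter_high = 50, amp_threshold = 100,
  epoch_s = 10,
  blocks = c("time", "freq", "nonlinear"),
  classifier = "rf", cv_mode = "intra",
  group_stats = FALSE,
  seed = 1L
)

#' Build a run configuration
#'
#' All pipeline settings with their defaults (the recording paradigm, the
#' synthetic attention effect, filter band, artifact threshold, feature
#' blocks, classifier and CV protocol, seed). Unknown keys are rejected;
#' band edges are validated against the Nyquist frequency before any
#' computation.
#'
#' @param ... Overrides of the defaults (see `attnfuse:::.CFG_DEFAULTS`).
#' @return Object of class `run_config`.
#' @export
run_config <- function(...) {
  over <- list(...)
  bad <- setdiff(names(over), names(.CFG_DEFAULTS))
  if (length(bad)) {
    stop("unknown config key(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  cfg <- modifyList(.CFG_DEFAULTS, over)
  if (cfg$filter_high >= cfg$fs / 2 || cfg$filter_low <= 0 ||
      cfg$filter_low >= cfg$filter_high) {
    stop("filter band must satisfy 0 < low < high < fs/2", call. = FALSE)
  }
  if (!cfg$cv_mode %in% c("intra", "loso")) {
    stop("cv_mode must be 'intra' or 'loso'", call. = FALSE)
  }
  structure(cfg, class = "run_config")
}

#' Write / read a configuration file
#'
#' YAML round-trip: `read_run_config(write_run_config(cfg, path))`
#' reproduces the configuration.
#'
#' @param cfg A `run_config`.
#' @param path YAML file path.
#' @return `path` (write) or a `run_config` (read).
#' @export
write_run_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  vals$n_subjects <- as.integer(vals$n_subjects)
  vals$n_trials <- as.integer(vals$n_trials)
  vals$seed <- as.integer(vals$seed)
  do.call(run_config, vals)
}

.cfg_paradigm <- function(cfg) {
  paradigm_spec(n_trials = cfg$n_trials, cue_s = cfg$cue_s,
                task_s = cfg$task_s, rest_s = cfg$rest_s, fs = cfg$fs,
                channels = if (is.null(cfg$channels)) EEG_CHANNELS else
                  cfg$channels)
}

.cfg_effect <- function(cfg) {
  effect_spec(band_gain = unlist(cfg$band_gain),
              affected_channels = cfg$affected_channels,
              noise_exponent = cfg$noise_exponent,
              artifact_rate = cfg$artifact_rate,
              subject_gain_sd = cfg$subject_gain_sd)
}

#' Preprocess one recording into clean epochs
#'
#' Band-pass filter, cut task segments into epochs, reject artifact
#' epochs.
#'
#' @param rec An `eeg_recording`.
#' @param cfg A `run_config`.
#' @return An `eeg_epochs`.
#' @export
preprocess_recording <- function(rec, cfg = run_config()) {
  rec <- bandpass_fir(rec, cfg$filter_low, cfg$filter_high)
  es <- segment_epochs(rec, epoch_s = cfg$epoch_s,
                       epochs_per_trial = floor(cfg$task_s / cfg$epoch_s))
  reject_artifacts(es, amp_threshold = cfg$amp_threshold)
}

#' Run the full pipeline
#'
#' Simulates a cohort, preprocesses every session, extracts the configured
#' feature blocks, runs the configured CV protocol (intra-subject per
#' subject, plus LOSO when requested) and optionally the group statistics.
#' Results, the configuration and a provenance manifest (config hash, seed,
#' output file hashes) are written under `out_dir`; re-running with an
#' identical configuration reproduces identical results.
#'
#' @param cfg A `run_config`.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with `designs`, `cv`, `group` and the paths
#'   written.
#' @export
run_pipeline <- function(cfg = run_config(), out_dir = tempfile("attnrun")) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paradigm <- .cfg_paradigm(cfg)
  effect <- .cfg_effect(cfg)

  message("[simulate] ", cfg$n_subjects, " subjects, ", cfg$n_trials,
          " trials each")
  cohort <- generate_cohort(cfg$n_subjects, paradigm, effect,
                            seed = cfg$seed)

  message("[preprocess] filtering ", cfg$filter_low, "-", cfg$filter_high,
          " Hz, threshold ", cfg$amp_threshold, " uV")
  epochs <- lapply(cohort, preprocess_recording, cfg = cfg)

  message("[extract] blocks: ", paste(cfg$blocks, collapse = "+"))
  designs <- lapply(epochs, build_design_matrix, blocks = cfg$blocks)
  message("[extract] ", nrow(designs[[1]]$X), " epochs x ",
          ncol(designs[[1]]$X), " features per subject")

  message("[classify] ", cfg$cv_mode, " CV with ", cfg$classifier)
  cv <- if (cfg$cv_mode == "loso") {
    loso_cv(designs, cfg$classifier, seed = cfg$seed)
  } else {
    res <- lapply(designs, intra_subject_cv, clf_name = cfg$classifier,
                  seed = cfg$seed)
    names(res) <- names(designs)
    res
  }

  group <- NULL
  if (isTRUE(cfg$group_stats)) {
    message("[groupstats] paired feature t-tests")
    means <- subject_state_means(designs)
    group <- list(p_values = paired_feature_ttests(means))
  }

  cv_json <- if (inherits(cv, "attn_cv")) {
    list(mode = cv$mode, clf = cv$classifier, block = cv$block,
         per_unit = unname(cv$accuracies), mean = cv$mean, sd = cv$sd)
  } else {
    lapply(cv, function(r) list(mode = r$mode, clf = r$classifier,
                                block = r$block,
                                per_unit = unname(r$accuracies),
                                mean = r$mean, sd = r$sd))
  }
  res_path <- file.path(out_dir, "results.json")
  jsonlite::write_json(cv_json, res_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  cfg_path <- file.path(out_dir, "config.yaml")
  write_run_config(cfg, cfg_path)
  if (!is.null(group)) {
    write.csv(group$p_values, file.path(out_dir, "feature_pvalues.csv"))
  }
  files <- setdiff(list.files(out_dir, full.names = TRUE),
                   file.path(out_dir, "manifest.json"))
  manifest <- list(
    config_hash = unname(tools::md5sum(cfg_path)),
    seed = cfg$seed,
    outputs = lapply(files, function(f)
      list(file = basename(f), md5 = unname(tools::md5sum(f))))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(designs = designs, cv = cv, group = group,
                 out_dir = out_dir))
}
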