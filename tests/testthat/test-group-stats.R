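# constructed designs and epoch sets keep these tests fast and exact

design_from_matrix <- function(X, labels, subject_id = "S01") {
  structure(list(X = X, labels = factor(labels),
                 info = data.frame(trial = seq_along(labels), epoch = 0,
                                   state = as.character(labels),
                                   subject_id = subject_id),
                 blocks = "freq", fs = 250,
                 channels = unique(sub(":.*$", "", colnames(X)))),
            class = "attn_design")
}

epochs_from_array <- function(arr, states, fs = 250,
                              channels = paste0("C", seq_len(dim(arr)[1]))) {
  structure(list(data = arr,
                 info = data.frame(trial = seq_along(states), epoch = 0,
                                   state = states, subject_id = "S01"),
                 fs = fs, channel_names = channels,
                 rejection_log = data.frame()),
            class = "eeg_epochs")
}

test_that("state means apply the 3-SD outlier rule", {
  # identical epochs: mean is the common value, nothing excluded
  X <- matrix(5, 20, 1, dimnames = list(NULL, "Fp1:bp_alpha"))
  lab <- rep(c("attention", "non_attention"), 10)
  m <- subject_state_means(list(S01 = design_from_matrix(X, lab)))
  expect_equal(unname(m[1, 1, ]), c(5, 5))
  # 19 values of 1.0 and one wild 100.0: the outlier is dropped
  v <- c(rep(1, 19), 100)
  X2 <- matrix(NA_real_, 40, 1, dimnames = list(NULL, "Fp1:bp_alpha"))
  lab2 <- rep(c("attention", "non_attention"), each = 20)
  X2[1:20, 1] <- v
  X2[21:40, 1] <- 1
  m2 <- subject_state_means(list(S01 = design_from_matrix(X2, lab2)))
  expect_equal(unname(m2[1, 1, "attention"]), 1)
  # permuting epochs changes nothing
  set.seed(50)
  perm <- sample(40)
  m3 <- subject_state_means(list(S01 = design_from_matrix(
    X2[perm, , drop = FALSE], lab2[perm])))
  expect_equal(m2, m3)
})

test_that("paired feature t-tests detect planted shifts and guard ties", {
  set.seed(51)
  ns <- 20
  mk <- function(shift) {
    X <- matrix(rnorm(40 * 2), 40, 2,
                dimnames = list(NULL, c("Fp1:bp_alpha", "O1:bp_beta")))
    lab <- rep(c("attention", "non_attention"), each = 20)
    X[lab == "attention", 1] <- X[lab == "attention", 1] + shift
    design_from_matrix(X, lab)
  }
  designs <- lapply(seq_len(ns), function(i) mk(-2))
  p <- paired_feature_ttests(subject_state_means(designs))
  expect_equal(dim(p), c(2, 2))
  expect_lt(p["Fp1", "bp_alpha"], 0.01)
  expect_gt(p["O1", "bp_beta"], 0.01)
  expect_true(all(p >= 0 & p <= 1, na.rm = TRUE))
  # zero-variance differences
  Xc <- matrix(1, 10, 1, dimnames = list(NULL, "Fp1:std"))
  dc <- design_from_matrix(Xc, rep(c("attention", "non_attention"), 5))
  pc <- paired_feature_ttests(subject_state_means(list(dc, dc, dc)))
  expect_equal(pc[1, 1], 1)
  expect_error(paired_feature_ttests(subject_state_means(list(dc, dc))),
               "3 subjects")
})

test_that("connectivity matrices are symmetric correlations per band", {
  set.seed(52)
  arr <- array(rnorm(3 * 2500 * 10), dim = c(3, 2500, 10))
  arr[3, , ] <- arr[1, , ]   # duplicated channel
  es <- epochs_from_array(arr, rep(c("attention", "non_attention"), 5))
  fc <- connectivity_fc(es)
  expect_named(fc, c("attention", "non_attention"))
  expect_named(fc$attention, names(attnfuse:::FC_BANDS))
  m <- fc$attention$theta
  expect_equal(m, t(m))
  expect_equal(unname(diag(m)), rep(1, 3))
  expect_true(all(m >= -1 & m <= 1))
  expect_equal(m[1, 3], 1, tolerance = 1e-9)
})

test_that("independent channels average to near-zero connectivity", {
  set.seed(53)
  arr <- array(rnorm(2 * 2500 * 60), dim = c(2, 2500, 60))
  es <- epochs_from_array(arr, rep(c("attention", "non_attention"), 30))
  fc <- connectivity_fc(es, bands = list(alpha = c(8, 13)))
  expect_lt(abs(fc$attention$alpha[1, 2]), 0.1)
  expect_lt(abs(fc$non_attention$alpha[1, 2]), 0.1)
})

test_that("FDR contrast flags a planted edge and controls the null", {
  set.seed(54)
  ns <- 20; nch <- 6
  mk_fc <- function(planted) {
    lapply(list(theta = 1), function(b) {
      m <- diag(nch)
      m[upper.tri(m)] <- rnorm(sum(upper.tri(m)), sd = 0.05)
      if (planted) m[1, 2] <- m[1, 2] + 0.5
      m[lower.tri(m)] <- t(m)[lower.tri(m)]
      diag(m) <- 1
      m
    })
  }
  att <- lapply(seq_len(ns), function(i) mk_fc(FALSE))
  non <- lapply(seq_len(ns), function(i) mk_fc(TRUE))
  res <- fc_group_test(att, non)
  expect_true(res$theta$mask[1, 2])
  expect_true(res$theta$mask[2, 1])
  expect_false(any(diag(res$theta$mask)))
  # adjusted p >= raw p everywhere
  ut <- upper.tri(res$theta$raw_p)
  expect_true(all(res$theta$adj_p[ut] >= res$theta$raw_p[ut] - 1e-12))
  # null: no spurious edges beyond the planted one
  expect_lte(sum(res$theta$mask[ut]) - 1, 2)
  # pure null
  non0 <- lapply(seq_len(ns), function(i) mk_fc(FALSE))
  res0 <- fc_group_test(att, non0)
  expect_lte(sum(res0$theta$mask[ut]), 2)
})

test_that("band topography normalises per subject and shows planted signs", {
  set.seed(55)
  channels <- c("Fp1", "Cz", "O1")
  bands <- names(attnfuse:::EEG_BANDS)
  mk <- function(reduced) {
    cols <- as.vector(outer(channels, paste0("bp_", bands),
                            function(a, b) paste0(a, ":", b)))
    X <- matrix(rnorm(40 * length(cols), mean = 10), 40, length(cols),
                dimnames = list(NULL, cols))
    lab <- rep(c("attention", "non_attention"), 20)
    if (reduced) {
      sel <- c("Fp1:bp_alpha", "O1:bp_alpha")
      X[lab == "attention", sel] <- X[lab == "attention", sel] - 5
    }
    design_from_matrix(X, lab)
  }
  designs <- lapply(1:6, function(i) mk(TRUE))
  topo <- band_topography(designs)
  expect_equal(dim(topo), c(5, 3, 2))
  dif <- topo["alpha", , "attention"] - topo["alpha", , "non_attention"]
  expect_lt(dif[["Fp1"]], 0)
  expect_lt(dif[["O1"]], 0)
  expect_gt(dif[["Fp1"]], -5)  # on the Z scale, not the raw scale
  # Z-scoring: pooled values per subject/band have mean 0, sd 1
  d <- designs[[1]]
  cols <- paste0(channels, ":bp_alpha")
  v <- d$X[, cols]
  z <- (v - mean(v)) / sd(as.vector(v))
  expect_equal(mean(z), 0, tolerance = 1e-9)
  expect_equal(sd(as.vector(z)), 1, tolerance = 1e-9)
})

test_that("Morlet maps localise tones and scale quadratically", {
  fs <- 250
  x <- sin(2 * pi * 10 * (0:2499) / fs)
  tfr <- morlet_tfr(x, fs, freqs = c(5, 10, 20))
  expect_equal(dim(tfr$power), c(3, 2500))
  mid <- 500:2000
  expect_gt(mean(tfr$power[2, mid]), 5 * mean(tfr$power[3, mid]))
  expect_true(all(tfr$power >= 0))
  tfr0 <- morlet_tfr(numeric(1000), fs, freqs = c(10))
  expect_equal(max(tfr0$power), 0)
  tfr2 <- morlet_tfr(2 * x, fs, freqs = c(5, 10, 20))
  expect_equal(tfr2$power, 4 * tfr$power, tolerance = 1e-9)
  expect_error(morlet_tfr(x, fs, freqs = c(10, 200)), "fs/2")
})
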