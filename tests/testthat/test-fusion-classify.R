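# small constructed design matrices (no EEG needed) for protocol tests
fake_design <- function(n = 120, p = 4, effect = 0, seed = 1,
                        subject_id = "S01") {
  set.seed(seed)
  labels <- factor(rep(rep(c("attention", "non_attention"), each = 6),
                       length.out = n))
  X <- matrix(rnorm(n * p), n, p,
              dimnames = list(NULL, paste0("Fp1:f", seq_len(p))))
  X[labels == "attention", 1] <- X[labels == "attention", 1] + effect
  structure(list(X = X, labels = labels,
                 info = data.frame(trial = rep(seq_len(ceiling(n / 6)),
                                               each = 6)[seq_len(n)],
                                   epoch = rep(0:5, ceiling(n / 6))[seq_len(n)],
                                   state = as.character(labels),
                                   subject_id = subject_id),
                 blocks = "time", fs = 250, channels = "Fp1"),
            class = "attn_design")
}

test_that("fusion concatenates blocks in order and injectively", {
  tb <- structure(rnorm(12), names = attnfuse:::TIME_FEATURE_NAMES)
  fb <- structure(rnorm(48), names = attnfuse:::FREQ_FEATURE_NAMES)
  db <- structure(rnorm(63), names = attnfuse:::NONLINEAR_FEATURE_NAMES)
  fused <- fuse(tb, fb, db)
  expect_length(fused, 123)
  expect_equal(unname(fused[1]), unname(tb[1]))
  expect_equal(unname(fused[13]), unname(fb[1]))
  expect_equal(unname(fused[61]), unname(db[1]))
  tb2 <- tb; tb2[5] <- tb2[5] + 1
  expect_false(identical(fuse(tb2, fb, db), fused))
  expect_error(fuse(tb[1:10], fb, db), "12")
})

test_that("design matrices have channel-major named columns", {
  es <- quick_epochs(seed = 9)
  d <- build_design_matrix(es, blocks = "time")
  expect_equal(dim(d$X), c(8, 4 * 12))
  expect_equal(colnames(d$X)[1], "Fp1:std")
  expect_equal(colnames(d$X)[13], "Fp2:std")
  expect_true(all(is.finite(d$X)))
  d1 <- build_design_matrix(es, blocks = "time", channels = "O1")
  expect_equal(ncol(d1$X), 12)
  expect_error(build_design_matrix(es, channels = "XX"), "unknown channel")
})

test_that("block subsetting pulls the registry columns", {
  d <- fake_design(p = 3)
  colnames(d$X) <- c("Fp1:std", "Fp1:bp_alpha", "Fp1:sampen")
  expect_equal(colnames(subset_block(d, "time")$X), "Fp1:std")
  expect_equal(colnames(subset_block(d, "freq")$X), "Fp1:bp_alpha")
  expect_equal(colnames(subset_block(d, "nonlinear")$X), "Fp1:sampen")
  expect_equal(ncol(subset_block(d, "fusion")$X), 3)
})

test_that("classifier contracts: configuration, separability, determinism", {
  set.seed(40)
  X <- rbind(matrix(rnorm(40, mean = 0), 20, 2),
             matrix(rnorm(40, mean = 4), 20, 2))
  colnames(X) <- c("a", "b")
  y <- rep(c("attention", "non_attention"), each = 20)
  for (nm in c("rf", "dt", "svm")) {
    clf <- make_classifier(nm)
    m <- clf$fit(X, y)
    expect_equal(mean(clf$predict(m, X) == y), 1)
    m2 <- make_classifier(nm)$fit(X, y)
    expect_identical(clf$predict(m, X), clf$predict(m2, X))
  }
  expect_error(make_classifier("xgb"), "arg")
  # linear SVM ignores a constant zero-weight direction
  clf <- make_classifier("svm")
  Xc <- cbind(X, c = 0)
  m <- clf$fit(Xc, y)
  Xshift <- Xc; Xshift[, "c"] <- 5
  expect_identical(clf$predict(m, Xc), clf$predict(m, Xshift))
})

test_that("chronological folds partition the epochs", {
  d <- fake_design(n = 123, effect = 3)
  cv <- intra_subject_cv(d, "dt", n_folds = 5)
  expect_s3_class(cv, "attn_cv")
  expect_length(cv$accuracies, 5)
  # folds: 4 x 24 + final 27, contiguous, covering all rows
  expect_equal(cv$mean, mean(cv$accuracies))
  expect_true(all(cv$accuracies >= 0 & cv$accuracies <= 1))
  # strong planted effect -> high accuracy even for a single tree
  expect_gt(cv$mean, 0.8)
})

test_that("label permutation drives accuracy to chance", {
  d <- fake_design(n = 120, effect = 0, seed = 2)
  set.seed(3)
  d$labels <- sample(d$labels)
  cv <- intra_subject_cv(d, "rf")
  expect_gte(cv$mean, 0.35)
  expect_lte(cv$mean, 0.65)
})

test_that("standardisation statistics come from the training fold only", {
  X <- matrix(c(1, 2, 3, 4, 1000, 2000), ncol = 1)
  sc <- fit_scaler(X[1:4, , drop = FALSE])
  expect_equal(sc$center, colMeans(X[1:4, , drop = FALSE]))
  Z <- apply_scaler(X[5:6, , drop = FALSE], sc)
  # test rows are transformed with training statistics, not their own
  expect_gt(Z[1], 100)
  # constant training column: guarded unit scale
  sc0 <- fit_scaler(matrix(1, 5, 1))
  expect_equal(sc0$scale, 1, ignore_attr = TRUE)
})

test_that("LOSO yields one accuracy per held-out subject", {
  designs <- lapply(1:5, function(i)
    fake_design(n = 48, effect = 3, seed = i,
                subject_id = sprintf("S%02d", i)))
  names(designs) <- sprintf("S%02d", 1:5)
  cv <- loso_cv(designs, "dt")
  expect_length(cv$accuracies, 5)
  expect_named(cv$accuracies, sprintf("S%02d", 1:5))
  expect_gt(cv$mean, 0.8)
  expect_error(loso_cv(designs[1], "dt"), "2 subjects")
  # no shared effect -> chance
  null_designs <- lapply(1:4, function(i)
    fake_design(n = 48, effect = 0, seed = 10 + i))
  cvn <- loso_cv(null_designs, "dt")
  expect_gte(cvn$mean, 0.3)
  expect_lte(cvn$mean, 0.7)
})

test_that("block comparison table covers blocks x classifiers", {
  es <- quick_epochs(seed = 12, channels = c("Fp1", "O1"))
  d <- build_design_matrix(es)
  designs <- list(S01 = d, S02 = d, S03 = d)
  res <- compare_feature_blocks(designs, clf_names = c("dt", "svm"),
                                n_folds = 4)
  expect_equal(nrow(res$table), 8)   # 4 blocks x 2 classifiers
  expect_true(all(res$table$mean_accuracy >= 0 &
                  res$table$mean_accuracy <= 1))
  expect_equal(dim(res$fusion_vs), c(3, 2))
  # identical accuracies across subjects trip the zero-variance guard
  expect_true(all(res$fusion_vs >= 0 & res$fusion_vs <= 1))
  same <- res$per_subject[, "fusion", 1] - res$per_subject[, "time", 1]
  if (sd(same) < 1e-12) expect_equal(res$fusion_vs["time", 1], 1)
})
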