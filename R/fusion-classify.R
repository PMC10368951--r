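# Feature fusion, design matrices and the two cross-validation protocols
# (chronological 5-fold within subject; leave-one-subject-out across
# subjects).

FUSION_FEATURE_NAMES <- c(TIME_FEATURE_NAMES, FREQ_FEATURE_NAMES,
                          NONLINEAR_FEATURE_NAMES)

#' Fuse the three per-channel feature blocks
#'
#' Order-preserving concatenation of the time-domain (12), frequency-domain
#' (48) and non-linear-dynamics (63) blocks into the 123-dimensional fused
#' vector.
#'
#' @param t_block,f_block,d_block Named numeric vectors of lengths 12, 48
#'   and 63.
#' @return Named numeric vector of length 123.
#' @export
fuse <- function(t_block, f_block, d_block) {
  if (length(t_block) != 12L) stop("time block must have 12 values", call. = FALSE)
  if (length(f_block) != 48L) stop("frequency block must have 48 values", call. = FALSE)
  if (length(d_block) != 63L) stop("non-linear block must have 63 values", call. = FALSE)
  out <- c(t_block, f_block, d_block)
  names(out) <- FUSION_FEATURE_NAMES
  out
}

.block_features <- function(x, fs, blocks) {
  out <- numeric(0)
  if ("time" %in% blocks) out <- c(out, time_features(x))
  if ("freq" %in% blocks) out <- c(out, freq_features(x, fs))
  if ("nonlinear" %in% blocks) out <- c(out, nonlinear_features(x, fs))
  out
}

#' Build the epoch-by-feature design matrix
#'
#' For every epoch, the selected feature blocks are computed per channel and
#' concatenated channel-major; column names are `CHANNEL:FEATURE`. Rows stay
#' in chronological epoch order.
#'
#' @param es An `eeg_epochs`.
#' @param blocks Subset of `c("time", "freq", "nonlinear")` (default: all
#'   three, the 123-dimensional fusion).
#' @param channels Channel labels to use (default: all channels in `es`).
#' @return Object of class `attn_design`: list with `X` (matrix), `labels`
#'   (factor), `info` (epoch metadata) and `blocks`.
#' @export
build_design_matrix <- function(es, blocks = c("time", "freq", "nonlinear"),
                                channels = NULL) {
  blocks <- match.arg(blocks, c("time", "freq", "nonlinear"),
                      several.ok = TRUE)
  n_ep <- dim(es$data)[3]
  if (n_ep == 0L) stop("empty epoch set", call. = FALSE)
  if (is.null(channels)) channels <- es$channel_names
  ci <- match(channels, es$channel_names)
  if (anyNA(ci)) stop("unknown channel(s): ",
                      paste(channels[is.na(ci)], collapse = ", "),
                      call. = FALSE)
  one <- .block_features(es$data[ci[1], , 1], es$fs, blocks)
  p <- length(one)
  cols <- as.vector(vapply(channels, function(ch)
    paste0(ch, ":", names(one)), character(p)))
  X <- matrix(NA_real_, n_ep, length(cols), dimnames = list(NULL, cols))
  for (k in seq_len(n_ep)) {
    row <- numeric(0)
    for (j in seq_along(ci)) {
      v <- .block_features(es$data[ci[j], , k], es$fs, blocks)
      if (any(!is.finite(v))) {
        stop("non-finite feature in epoch ", k, ", channel ", channels[j],
             ", feature ", names(v)[which(!is.finite(v))[1]], call. = FALSE)
      }
      row <- c(row, v)
    }
    X[k, ] <- row
  }
  structure(
    list(X = X, labels = factor(es$info$state), info = es$info,
         blocks = blocks, fs = es$fs, channels = channels),
    class = "attn_design"
  )
}

#' Restrict a design matrix to one feature block
#'
#' @param design An `attn_design` built with all blocks.
#' @param block `"time"`, `"freq"`, `"nonlinear"` or `"fusion"`.
#' @return An `attn_design` with only that block's columns.
#' @export
subset_block <- function(design, block) {
  if (block == "fusion") return(design)
  reg <- switch(block, time = TIME_FEATURE_NAMES, freq = FREQ_FEATURE_NAMES,
                nonlinear = NONLINEAR_FEATURE_NAMES,
                stop("unknown block: ", block, call. = FALSE))
  feat <- sub("^[^:]+:", "", colnames(design$X))
  out <- design
  out$X <- design$X[, feat %in% reg, drop = FALSE]
  out$blocks <- block
  out
}

# --- classifiers ------------------------------------------------------------

#' Construct a classifier contract
#'
#' Returns a fit/predict pair for one of the three classifiers: random
#' forest (100 trees, Gini impurity), decision tree (information-entropy
#' criterion, best splits) or support-vector machine (linear kernel,
#' penalty C = 2; features must be standardised, which the CV drivers do
#' using training-fold statistics only). Any stochastic component is
#' seeded, so repeated fits on the same data give identical predictions.
#'
#' @param name `"rf"`, `"dt"` or `"svm"`.
#' @param seed Seed for stochastic classifiers (default 42).
#' @return List with elements `name`, `fit(X, y)`, `predict(model, X)` and
#'   `scale` (whether the CV driver should standardise features).
#' @export
make_classifier <- function(name = c("rf", "dt", "svm"), seed = 42L) {
  name <- match.arg(name)
  switch(name,
    rf = list(
      name = "rf", scale = FALSE,
      fit = function(X, y) {
        set.seed(seed)
        randomForest::randomForest(x = X, y = factor(y), ntree = 100)
      },
      predict = function(model, X) as.character(predict(model, X))
    ),
    dt = list(
      name = "dt", scale = FALSE,
      fit = function(X, y) {
        df <- data.frame(X, check.names = TRUE)
        df$.y <- factor(y)
        rpart::rpart(.y ~ ., data = df, method = "class",
                     parms = list(split = "information"))
      },
      predict = function(model, X) {
        as.character(predict(model, data.frame(X, check.names = TRUE),
                             type = "class"))
      }
    ),
    svm = list(
      name = "svm", scale = TRUE,
      # the configured kernel coefficient (gamma 0.2) is recorded but has
      # no effect on a linear kernel
      fit = function(X, y) {
        e1071::svm(x = X, y = factor(y), kernel = "linear", cost = 2,
                   gamma = 0.2, scale = FALSE)
      },
      predict = function(model, X) as.character(predict(model, X))
    )
  )
}

#' Fit feature standardisation on training data
#'
#' @param X Training-fold feature matrix.
#' @return List with `center` and `scale` (zero-variance columns get scale
#'   1).
#' @export
fit_scaler <- function(X) {
  ctr <- colMeans(X)
  scl <- apply(X, 2, sd)
  scl[scl < .EPS] <- 1
  list(center = ctr, scale = scl)
}

#' Apply a fitted standardisation
#'
#' @param X Feature matrix.
#' @param scaler Result of [fit_scaler()].
#' @return Standardised matrix.
#' @export
apply_scaler <- function(X, scaler) {
  sweep(sweep(X, 2, scaler$center), 2, scaler$scale, "/")
}

.fit_predict <- function(clf, Xtr, ytr, Xte) {
  if (clf$scale) {
    sc <- fit_scaler(Xtr)
    Xtr <- apply_scaler(Xtr, sc)
    Xte <- apply_scaler(Xte, sc)
  }
  model <- clf$fit(Xtr, ytr)
  clf$predict(model, Xte)
}

.cv_result <- function(acc, clf_name, mode, block_tag) {
  structure(
    list(accuracies = acc, mean = mean(acc), sd = sd(acc),
         classifier = clf_name, mode = mode, block = block_tag),
    class = "attn_cv"
  )
}

#' @export
print.attn_cv <- function(x, ...) {
  cat(sprintf("<attn_cv> %s CV, classifier %s, block %s\n", x$mode,
              x$classifier, x$block))
  cat(sprintf("  accuracy %.4f +/- %.4f over %d %s\n", x$mean,
              if (is.na(x$sd)) 0 else x$sd, length(x$accuracies),
              if (x$mode == "loso") "subjects" else "folds"))
  invisible(x)
}

#' @export
summary.attn_cv <- function(object, ...) {
  print(object)
  print(round(object$accuracies, 4))
  invisible(object)
}

#' Chronological k-fold cross-validation within one subject
#'
#' The chronological epoch sequence is split into `n_folds` contiguous
#' blocks (remainder epochs go to the last fold); each block serves once as
#' the test set, preserving the temporal train/test separation.
#'
#' @param design An `attn_design` for one subject.
#' @param clf_name `"rf"`, `"dt"` or `"svm"`.
#' @param n_folds Number of folds (default 5).
#' @param seed Classifier seed.
#' @return An `attn_cv` with one accuracy per fold.
#' @export
intra_subject_cv <- function(design, clf_name = "rf", n_folds = 5L,
                             seed = 42L) {
  n <- nrow(design$X)
  if (n < n_folds) stop("fewer epochs than folds", call. = FALSE)
  base <- n %/% n_folds
  sizes <- rep(base, n_folds)
  sizes[n_folds] <- sizes[n_folds] + n - base * n_folds
  ends <- cumsum(sizes)
  starts <- c(1L, head(ends, -1L) + 1L)
  clf <- make_classifier(clf_name, seed = seed)
  acc <- numeric(n_folds)
  for (f in seq_len(n_folds)) {
    te <- starts[f]:ends[f]
    tr <- setdiff(seq_len(n), te)
    ytr <- design$labels[tr]
    if (length(unique(ytr)) < 2L) {
      stop("a class is absent from the training split of fold ", f,
           "; review stratification", call. = FALSE)
    }
    pred <- .fit_predict(clf, design$X[tr, , drop = FALSE], ytr,
                         design$X[te, , drop = FALSE])
    acc[f] <- mean(pred == as.character(design$labels[te]))
  }
  names(acc) <- paste0("fold", seq_len(n_folds))
  .cv_result(acc, clf_name, "intra",
             paste(design$blocks, collapse = "+"))
}

#' Leave-one-subject-out cross-validation
#'
#' Each subject's design matrix is held out once while all other subjects
#' train the classifier; one accuracy per held-out subject.
#'
#' @param designs List of `attn_design`, one per subject.
#' @param clf_name `"rf"`, `"dt"` or `"svm"`.
#' @param seed Classifier seed.
#' @return An `attn_cv` with one accuracy per subject.
#' @export
loso_cv <- function(designs, clf_name = "rf", seed = 42L) {
  if (length(designs) < 2L) {
    stop("LOSO needs at least 2 subjects", call. = FALSE)
  }
  clf <- make_classifier(clf_name, seed = seed)
  ids <- names(designs)
  if (is.null(ids)) ids <- paste0("S", seq_along(designs))
  acc <- vapply(seq_along(designs), function(i) {
    Xtr <- do.call(rbind, lapply(designs[-i], function(d) d$X))
    ytr <- unlist(lapply(designs[-i], function(d) as.character(d$labels)))
    pred <- .fit_predict(clf, Xtr, ytr, designs[[i]]$X)
    mean(pred == as.character(designs[[i]]$labels))
  }, numeric(1))
  names(acc) <- ids
  .cv_result(acc, clf_name, "loso",
             paste(designs[[1]]$blocks, collapse = "+"))
}

#' Compare feature blocks across classifiers
#'
#' Runs chronological k-fold CV per subject for each feature block (time,
#' frequency, non-linear, fusion) and classifier, and paired t-tests of the
#' fusion block's per-subject mean accuracy against each single block.
#'
#' @param designs List of full (all-blocks) `attn_design`, one per subject.
#' @param clf_names Classifiers to run (default all three).
#' @param n_folds,seed Passed to [intra_subject_cv()].
#' @return List with `table` (block x classifier mean/sd accuracy) and
#'   `fusion_vs` (paired t-test p-values of fusion against each block per
#'   classifier; identical accuracies give p = 1).
#' @export
compare_feature_blocks <- function(designs, clf_names = c("rf", "dt", "svm"),
                                   n_folds = 5L, seed = 42L) {
  blocks <- c("time", "freq", "nonlinear", "fusion")
  per_subj <- array(NA_real_,
                    dim = c(length(designs), length(blocks),
                            length(clf_names)),
                    dimnames = list(NULL, blocks, clf_names))
  for (i in seq_along(designs)) {
    for (b in blocks) {
      d <- subset_block(designs[[i]], b)
      for (cl in clf_names) {
        per_subj[i, b, cl] <-
          intra_subject_cv(d, cl, n_folds = n_folds, seed = seed)$mean
      }
    }
  }
  tab <- expand.grid(block = blocks, classifier = clf_names,
                     stringsAsFactors = FALSE)
  tab$mean_accuracy <- mapply(function(b, cl) mean(per_subj[, b, cl]),
                              tab$block, tab$classifier)
  tab$sd_accuracy <- mapply(function(b, cl) sd(per_subj[, b, cl]),
                            tab$block, tab$classifier)
  pv <- sapply(clf_names, function(cl) {
    vapply(c("time", "freq", "nonlinear"), function(b) {
      d <- per_subj[, "fusion", cl] - per_subj[, b, cl]
      if (sd(d) < .EPS) return(1)
      t.test(d)$p.value
    }, numeric(1))
  })
  list(table = tab, fusion_vs = pv, per_subject = per_subj)
}
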