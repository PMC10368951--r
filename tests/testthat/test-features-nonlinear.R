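test_that("Teager-Kaiser energy obeys its defining identity", {
  # psi of A cos(omega n) is A^2 sin^2(omega) at every interior sample
  A <- 2; om <- 0.3
  x <- A * cos(om * (0:199))
  psi <- teager_kaiser(x)
  expect_equal(psi, rep(A^2 * sin(om)^2, 198), tolerance = 1e-10)
  # direct element-wise evaluation oracle
  set.seed(30)
  y <- rnorm(100)
  direct <- sapply(2:99, function(n) y[n]^2 - y[n - 1] * y[n + 1])
  expect_equal(teager_kaiser(y), direct, tolerance = 1e-12)
  expect_equal(teager_kaiser(rep(3, 50)), rep(0, 48))
})

test_that("Teager-Kaiser wavelet block has 14 values over 7 sets", {
  set.seed(31)
  v <- teager_kaiser_features(rnorm(2500))
  expect_length(v, 14)
  expect_match(names(v)[1], "tk_mean_a6")
  expect_match(names(v)[14], "tk_sd_d1")
  expect_error(teager_kaiser_features(rnorm(70)),
               "fewer than 3|too short")
})

test_that("wavelet entropy terms behave like a probability distribution", {
  set.seed(32)
  x <- rnorm(2560)
  co <- dwt_decompose(x, 6)
  # engineered equal energies via reconstruction -> every term (1/7) ln 7
  co_eq <- lapply(co, function(c) c / sqrt(sum(c^2)))
  names(co_eq) <- names(co)
  we_eq <- wavelet_entropy(dwt_reconstruct(co_eq))
  expect_equal(unname(we_eq), rep(log(7) / 7, 7), tolerance = 1e-6)
  expect_equal(sum(we_eq), log(7), tolerance = 1e-6)
  # all energy in one set -> all terms zero
  co_one <- lapply(co, function(c) c * 0)
  co_one[["D3"]] <- co[["D3"]]
  names(co_one) <- names(co)
  we_one <- wavelet_entropy(dwt_reconstruct(co_one))
  expect_equal(unname(we_one), rep(0, 7), tolerance = 1e-9)
  # random signal: probabilities sum to 1, entropy bounded by ln 7
  e <- vapply(co, function(c) sum(c^2), numeric(1))
  expect_equal(sum(e / sum(e)), 1, tolerance = 1e-9)
  expect_lte(sum(wavelet_entropy(x)), log(7))
  expect_error(wavelet_entropy(numeric(2500)), "zero-energy")
})

test_that("entropy families give closed-form values on uniform spectra", {
  flat <- structure(list(freq = 0:125, power = rep(1, 126), df = 1),
                    class = "attn_spectrum")
  sh <- entropy_family(flat, "shannon")
  re <- entropy_family(flat, "renyi", q = 2)
  ts <- entropy_family(flat, "tsallis", q = 2)
  expect_length(sh, 10); expect_length(re, 10); expect_length(ts, 10)
  # band b spans k whole-Hz bins -> uniform entropy ln k
  k5 <- length(which(flat$freq >= 7 & flat$freq < 10))
  expect_equal(unname(sh[5]), log(k5), tolerance = 1e-9)
  expect_equal(unname(re[5]), log(k5), tolerance = 1e-9)
  expect_equal(unname(ts[5]), 1 - 1 / k5, tolerance = 1e-9)
  # Renyi order q -> 1 approaches Shannon
  set.seed(33)
  spr <- structure(list(freq = 0:125, power = runif(126), df = 1),
                   class = "attn_spectrum")
  expect_lt(max(abs(entropy_family(spr, "renyi", q = 1.001) -
                    entropy_family(spr, "shannon"))), 0.01)
})

test_that("sample and approximate entropy match the O(N^2) oracle", {
  set.seed(34)
  x <- rnorm(300)
  r <- 0.2 * sd(x)
  v <- regularity_entropies(x, m = 2, r = r)
  expect_equal(v[["sampen"]], oracle_sampen(x, 2, r), tolerance = 1e-10)
  expect_equal(v[["apen"]], oracle_apen(x, 2, r), tolerance = 1e-10)
  # strictly periodic signal is highly regular
  per <- sin(2 * pi * 25 * (0:299) / 250)
  expect_lt(regularity_entropies(per)[["sampen"]], 0.2)
  expect_equal(regularity_entropies(rep(1, 300)), c(sampen = 0, apen = 0))
})

test_that("noise is less regular than a sinusoid of equal variance", {
  for (s in 1:10) {
    set.seed(s)
    noise <- rnorm(300, sd = sqrt(0.5))
    tone <- sin(2 * pi * 10 * (0:299) / 250)
    expect_gt(regularity_entropies(noise)[["sampen"]],
              regularity_entropies(tone)[["sampen"]])
  }
})

test_that("fractal dimensions hit their known limits", {
  expect_equal(fractal_dims(seq(0, 1, length.out = 500))[["katz"]], 1,
               tolerance = 0.01)
  set.seed(35)
  expect_equal(fractal_dims(rnorm(10000))[["higuchi"]], 2, tolerance = 0.1)
  # Petrosian on an alternating series: every interior sample is a
  # sign-change of the first difference
  alt <- rep(c(1, -1), 150)
  n <- 300; nd <- sum(diff(sign(diff(alt))) != 0)
  expect_equal(fractal_dims(alt)[["petrosian"]],
               log10(n) / (log10(n) + log10(n / (n + 0.4 * nd))))
  expect_equal(fractal_dims(rep(2, 300)),
               c(petrosian = 1, higuchi = 1, katz = 1))
})

test_that("complexity measures behave on canonical inputs", {
  set.seed(36)
  expect_equal(permutation_entropy(1:300), 0)
  cm <- complexity_misc(rnorm(2500), 250)
  expect_named(cm, c("spectral_entropy", "svd_entropy", "svd_fisher",
                     "perm_entropy", "hurst", "dfa", "line_length"))
  expect_equal(complexity_misc(rep(1, 2500), 250)[["line_length"]], 0)
  x <- rnorm(2500)
  expect_equal(complexity_misc(x, 250)[["line_length"]],
               sum(abs(diff(x))))
})

test_that("DFA exponents recover white and Brownian scaling", {
  a_w <- mean(sapply(1:5, function(s) {
    set.seed(s); dfa_exponent(rnorm(5000))
  }))
  a_b <- mean(sapply(1:5, function(s) {
    set.seed(s); dfa_exponent(cumsum(rnorm(5000)))
  }))
  expect_equal(a_w, 0.5, tolerance = 0.1)
  expect_equal(a_b, 1.5, tolerance = 0.1)
})

test_that("non-linear feature vector layout and scale invariance", {
  set.seed(37)
  x <- rnorm(2500)
  v <- nonlinear_features(x, 250)
  expect_length(v, 63)
  expect_identical(names(v), attnfuse:::NONLINEAR_FEATURE_NAMES)
  expect_true(all(is.finite(v)))
  expect_equal(1 + 1 + 1 + 1 + 1 + 10 + 10 + 10 + 1 + 1 + 1 + 1 + 7 + 14 +
                 1 + 1 + 1, 63)
  v2 <- nonlinear_features(2 * x, 250)
  invariant <- c("perm_entropy", "petrosian_fd", "higuchi_fd", "dfa")
  expect_equal(v2[invariant], v[invariant], tolerance = 1e-6)
  # entropies non-negative
  ent <- grep("renyi|tsallis|shannon|went|sampen|apen|spectral_entropy",
              names(v))
  expect_true(all(v[ent] >= -1e-12))
})
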