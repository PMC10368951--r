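# Discrete wavelet transform (Mallat pyramid, periodized extension).
# Orthonormal filters: with periodization and even input length every
# analysis step is an orthonormal map, so sum of squared coefficients
# equals sum of squared samples. Odd-length inputs are extended by
# repeating the final sample before a step (Parseval then holds only
# approximately at that step).

.WAVELETS <- list(
  haar = c(1, 1) / sqrt(2),
  db2 = c(0.482962913144690, 0.836516303737469,
          0.224143868041857, -0.129409522550921),
  db4 = c(0.230377813308855, 0.714846570552541,
          0.630880767929590, -0.027983769416984,
          -0.187034811718881, 0.030841381835987,
          0.032883011666983, -0.010597401784997)
)

dwt_filters <- function(wavelet) {
  h <- .WAVELETS[[wavelet]]
  if (is.null(h)) stop("unknown wavelet: ", wavelet, call. = FALSE)
  L <- length(h)
  g <- rev(h) * (-1)^(seq_len(L) - 1)
  list(lo = h, hi = g)
}

# One analysis step: periodic convolution + dyadic downsampling.
.dwt_step <- function(x, flt) {
  n <- length(x)
  if (n %% 2L == 1L) {
    x <- c(x, x[n])
    n <- n + 1L
  }
  half <- n %/% 2L
  k2 <- 2L * (seq_len(half) - 1L)
  a <- numeric(half)
  d <- numeric(half)
  L <- length(flt$lo)
  for (m in seq_len(L)) {
    idx <- (k2 + (m - 1L)) %% n + 1L
    a <- a + flt$lo[m] * x[idx]
    d <- d + flt$hi[m] * x[idx]
  }
  list(approx = a, detail = d)
}

#' Multilevel discrete wavelet decomposition
#'
#' Decomposes a signal into `level` detail coefficient sets plus one final
#' approximation set using a Daubechies orthonormal filter bank with
#' periodized boundary handling.
#'
#' @param x Numeric vector.
#' @param level Decomposition depth (default 6).
#' @param wavelet One of `"haar"`, `"db2"`, `"db4"` (default `"db4"`).
#' @return Named list of coefficient vectors, coarse to fine:
#'   `A<level>`, `D<level>`, ..., `D1`.
#' @examples
#' co <- dwt_decompose(rnorm(256), level = 6)
#' names(co)
#' @export
dwt_decompose <- function(x, level = 6L, wavelet = "db4") {
  if (length(x) < 2^level) {
    stop("signal too short for a ", level, "-level decomposition",
         call. = FALSE)
  }
  flt <- dwt_filters(wavelet)
  details <- vector("list", level)
  cur <- as.numeric(x)
  for (j in seq_len(level)) {
    st <- .dwt_step(cur, flt)
    details[[j]] <- st$detail
    cur <- st$approx
  }
  out <- c(list(cur), rev(details))
  names(out) <- c(paste0("A", level), paste0("D", level:1))
  out
}

# One synthesis step (adjoint of .dwt_step; exact inverse for even input)
.idwt_step <- function(a, d, flt) {
  half <- length(a)
  n <- 2L * half
  x <- numeric(n)
  k2 <- 2L * (seq_len(half) - 1L)
  L <- length(flt$lo)
  for (m in seq_len(L)) {
    idx <- (k2 + (m - 1L)) %% n + 1L
    add <- flt$lo[m] * a + flt$hi[m] * d
    # scatter-add; idx values repeat across k when L > 2, so accumulate
    x <- x + tabulate_add(idx, add, n)
  }
  x
}

tabulate_add <- function(idx, vals, n) {
  out <- numeric(n)
  reps <- split(vals, idx)
  out[as.integer(names(reps))] <- vapply(reps, sum, numeric(1))
  out
}

#' Reconstruct a signal from its wavelet decomposition
#'
#' Inverse of [dwt_decompose()] for inputs whose length is divisible by
#' `2^level` (the periodized orthonormal transform is then exactly
#' invertible).
#'
#' @param coefs Named coefficient list as returned by [dwt_decompose()].
#' @param wavelet The wavelet used for decomposition.
#' @return Numeric vector.
#' @export
dwt_reconstruct <- function(coefs, wavelet = "db4") {
  flt <- dwt_filters(wavelet)
  level <- length(coefs) - 1L
  cur <- coefs[[1]]
  for (j in level:1) {
    cur <- .idwt_step(cur, coefs[[paste0("D", j)]], flt)
  }
  cur
}

#' Wavelet sub-band energies of the detail levels
#'
#' Energy of each detail coefficient set, \eqn{E_j = \sum_k |C(j,k)|^2},
#' for levels j = 1..`level` of a Daubechies decomposition.
#'
#' @inheritParams dwt_decompose
#' @return Numeric vector of `level` energies, named `wav_energy_d1` (finest)
#'   through `wav_energy_d<level>`.
#' @export
dwt_energies <- function(x, level = 6L, wavelet = "db4") {
  co <- dwt_decompose(x, level = level, wavelet = wavelet)
  e <- vapply(level:1, function(j) sum(co[[paste0("D", j)]]^2), numeric(1))
  e <- rev(e)  # order D1..Dlevel
  names(e) <- paste0("wav_energy_d", seq_len(level))
  e
}
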