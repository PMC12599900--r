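#' @useDynLib pcgatoms, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic 31-bit sub-seed derived from a base seed and integer tags.
derive_seed <- function(seed, ...) {
  tags <- c(...)
  x <- as.double(seed) %% 2147483647
  for (t in tags) {
    x <- (x * 48271 + as.double(t) + 1) %% 2147483647
  }
  as.integer(x)
}

#' Cross-correlation between two equal-length signals over a lag window
#'
#' Computes `C(l) = sum_t x(t) * y(t + l)` for integer lags `l` in
#' `[-max_lag, max_lag]` via FFT. A positive argmax lag means `y` contains the
#' content of `x` shifted `l` samples earlier (i.e. `y(t) = x(t - l)` peaks at
#' `l` equal to the delay of `y` relative to `x`... see [beamform()]).
#'
#' @param x,y numeric vectors of equal length.
#' @param max_lag maximum absolute lag, in samples.
#' @return list with `lags` and `values`.
#' @keywords internal
xcorr_lagged <- function(x, y, max_lag) {
  n <- length(x)
  stopifnot(length(y) == n, max_lag < n)
  m <- stats::nextn(n + max_lag, 2)
  X <- stats::fft(c(x, numeric(m - n)))
  Y <- stats::fft(c(y, numeric(m - n)))
  # circular cross-correlation sum_t x(t) y(t+l)  (l mod m)
  cc <- Re(stats::fft(Conj(X) * Y, inverse = TRUE)) / m
  lags <- -max_lag:max_lag
  idx <- ifelse(lags >= 0, lags + 1, m + lags + 1)
  list(lags = lags, values = cc[idx])
}

# L2 norm squared
energy <- function(x) sum(x^2)

snr_db <- function(signal_power, noise_power) 10 * log10(signal_power / noise_power)

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_if_not_finite <- function(x, what) {
  if (!all(is.finite(x))) stop(sprintf("non-finite values in %s", what), call. = FALSE)
  invisible(TRUE)
}
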