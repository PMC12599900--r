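# IIR filtering utilities.
#
# No DSP package (signal/gsignal) ships with the target library, so the
# Butterworth band-pass used on cluster reconstructions is designed here from
# first principles: analog prototype poles -> band-pass transform -> bilinear
# transform -> second-order sections. The magnitude response is validated in
# the test suite against reference values at the design frequencies.

#' Design a Butterworth band-pass filter as second-order sections
#'
#' @param order prototype (low-pass) order `n`; the band-pass filter has order
#'   `2n`. The reconstruction pipeline uses `order = 5`, i.e. a 5th-order
#'   Butterworth band-pass.
#' @param low,high band edges in Hz.
#' @param fs sampling rate in Hz.
#' @return a `sections x 6` matrix, each row `(b0, b1, b2, 1, a1, a2)`.
#' @export
butter_bandpass <- function(order, low, high, fs) {
  stopifnot(order >= 1, low > 0, high > low, high < fs / 2)
  fs2 <- 2 * fs
  w1 <- fs2 * tan(pi * low / fs)   # prewarped rad/s
  w2 <- fs2 * tan(pi * high / fs)
  bw <- w2 - w1
  w0 <- sqrt(w1 * w2)

  k <- seq_len(order)
  proto <- exp(1i * pi * (2 * k + order - 1) / (2 * order))  # Re < 0

  # low-pass -> band-pass: s_lp = (s^2 + w0^2) / (bw * s)
  poles <- c()
  for (p in proto) {
    disc <- sqrt((bw * p / 2)^2 - w0^2 + 0i)
    poles <- c(poles, bw * p / 2 + disc, bw * p / 2 - disc)
  }
  # bilinear transform
  zp <- (fs2 + poles) / (fs2 - poles)

  # pair complex-conjugate poles into biquads; each section gets zeros at +1, -1
  upper <- zp[Im(zp) > 1e-12]
  realp <- Re(zp[abs(Im(zp)) <= 1e-12])
  sections <- list()
  for (p in upper[order(-Mod(upper))]) {
    a <- c(1, -2 * Re(p), Mod(p)^2)
    sections[[length(sections) + 1L]] <- c(1, 0, -1, a)
  }
  realp <- sort(realp)
  while (length(realp) >= 2) {
    p1 <- realp[1]; p2 <- realp[2]; realp <- realp[-(1:2)]
    sections[[length(sections) + 1L]] <- c(1, 0, -1, 1, -(p1 + p2), p1 * p2)
  }
  sos <- do.call(rbind, sections)

  # normalize to unit gain at the (digital) geometric center frequency
  wc <- 2 * atan(w0 / fs2)
  z <- exp(1i * wc)
  h <- prod(apply(sos, 1, function(s) {
    (s[1] + s[2] / z + s[3] / z^2) / (s[4] + s[5] / z + s[6] / z^2)
  }))
  sos[1, 1:3] <- sos[1, 1:3] / Mod(h)
  sos
}

#' Magnitude response of a second-order-section filter
#'
#' @param sos section matrix from [butter_bandpass()].
#' @param freqs frequencies in Hz.
#' @param fs sampling rate in Hz.
#' @return magnitude (linear) at each frequency.
#' @export
sos_response <- function(sos, freqs, fs) {
  vapply(freqs, function(f) {
    z <- exp(1i * 2 * pi * f / fs)
    Mod(prod(apply(sos, 1, function(s) {
      (s[1] + s[2] / z + s[3] / z^2) / (s[4] + s[5] / z + s[6] / z^2)
    })))
  }, numeric(1))
}

#' Apply a second-order-section filter (single pass)
#' @keywords internal
sos_filter <- function(sos, x) {
  sosfilt_cpp(sos, as.numeric(x))
}

#' Zero-phase (forward-backward) second-order-section filtering
#'
#' Odd-reflection padding at both ends limits startup transients; the double
#' pass squares the magnitude response and cancels the phase response, so
#' filtered reconstructions stay aligned with the cardiac timeline.
#'
#' @param sos section matrix.
#' @param x numeric signal.
#' @return filtered signal, same length as `x`.
#' @export
sos_filtfilt <- function(sos, x) {
  n <- length(x)
  if (n < 2) return(x)
  pad <- min(n - 1, 3 * (2 * nrow(sos) + 1) * 4)
  # odd extension
  pre <- 2 * x[1] - x[seq(pad + 1, 2)]
  post <- 2 * x[n] - x[seq(n - 1, n - pad)]
  ext <- c(pre, x, post)
  y <- sos_filter(sos, ext)
  y <- rev(sos_filter(sos, rev(y)))
  y[(pad + 1):(pad + n)]
}

#' Gaussian smoothing of a signal
#'
#' Convolution with a normalized Gaussian kernel (radius `4 * sigma`) using
#' reflection padding at the edges.
#'
#' @param x numeric signal.
#' @param sigma kernel standard deviation, in samples.
#' @return smoothed signal, same length as `x`.
#' @export
gauss_smooth <- function(x, sigma) {
  if (sigma <= 0) return(x)
  r <- max(1L, ceiling(4 * sigma))
  k <- stats::dnorm(-r:r, sd = sigma)
  k <- k / sum(k)
  n <- length(x)
  if (n == 1) return(x)
  # mirror-fold indices 1-r .. n+r into [1, n] (reflection padding)
  t <- (1 - r):(n + r)
  p <- 2 * n - 2
  t2 <- ((t - 1) %% p)
  pos <- t2 + 1
  pos[pos > n] <- 2 * n - pos[pos > n]
  ext <- x[pos]
  y <- stats::convolve(ext, rev(k), type = "filter")
  stopifnot(length(y) == n)
  y
}
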