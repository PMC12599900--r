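# Short-time Fourier transform band power (Welch-style integration).

hann_window <- function(n) 0.5 * (1 - cos(2 * pi * (0:(n - 1)) / n))

#' Short-time Fourier transform power per frame
#'
#' Frames of `win` samples at hop `hop`, Hann windowed; only fully contained
#' frames are used. Power is scaled as a one-sided PSD so that integrating
#' over frequency recovers signal power (variance) in squared signal units.
#'
#' @param x numeric signal.
#' @param fs sampling rate in Hz.
#' @param win window length in samples (default 256).
#' @param hop hop size in samples (default 128).
#' @return list with `psd` (frames x bins one-sided PSD matrix), `freqs` (Hz),
#'   and `df` (bin spacing, Hz).
#' @export
stft_psd <- function(x, fs, win = 256L, hop = 128L) {
  n <- length(x)
  if (n < win) stop("signal shorter than one STFT window")
  w <- hann_window(win)
  starts <- seq(1L, n - win + 1L, by = hop)
  frames <- vapply(starts, function(s) x[s:(s + win - 1L)] * w, numeric(win))
  spec <- stats::mvfft(frames)                 # win x n_frames
  nbin <- win %/% 2 + 1L
  p <- Mod(spec[seq_len(nbin), , drop = FALSE])^2
  scale <- 1 / (fs * sum(w^2))
  p <- p * scale
  p[2:(nbin - 1L), ] <- 2 * p[2:(nbin - 1L), ]  # one-sided doubling
  list(psd = t(p), freqs = (seq_len(nbin) - 1L) * fs / win, df = fs / win)
}

#' Mean power in fixed frequency bands
#'
#' Integrates the mean (over frames) one-sided PSD within each band. Band
#' membership is half-open `[low, high)`; the final band is closed at the top
#' edge so the full analysis range is covered.
#'
#' @param x numeric signal.
#' @param fs sampling rate in Hz.
#' @param band_edges increasing band edges in Hz (default `seq(0, 400, 50)`,
#'   i.e. eight 50-Hz bands from 0 to 400 Hz).
#' @param win,hop STFT parameters.
#' @return named numeric vector of band powers (squared signal units).
#' @export
band_powers <- function(x, fs, band_edges = seq(0, 400, by = 50),
                        win = 256L, hop = 128L) {
  s <- stft_psd(x, fs, win, hop)
  mean_psd <- colMeans(s$psd)
  nb <- length(band_edges) - 1L
  out <- numeric(nb)
  names(out) <- paste0(band_edges[-length(band_edges)], "-", band_edges[-1], "Hz")
  top <- band_edges[length(band_edges)]
  for (i in seq_len(nb)) {
    lo <- band_edges[i]; hi <- band_edges[i + 1L]
    sel <- if (hi == top) s$freqs >= lo & s$freqs <= hi else s$freqs >= lo & s$freqs < hi
    out[i] <- sum(mean_psd[sel]) * s$df
  }
  out
}

# Band power computed directly from one periodogram (used as an internal
# cross-check and by the synthetic-data tests).
periodogram_band_power <- function(x, fs, low, high) {
  n <- length(x)
  p <- Mod(stats::fft(x))^2 / (fs * n)
  nbin <- n %/% 2 + 1L
  p <- p[seq_len(nbin)]
  p[2:(nbin - 1L)] <- 2 * p[2:(nbin - 1L)]
  freqs <- (seq_len(nbin) - 1L) * fs / n
  sel <- freqs >= low & freqs <= high
  sum(p[sel]) * fs / n
}
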