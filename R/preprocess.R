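# Preprocessing: delay-and-sum beamforming, sliding windows, a simplified
# S2 detector (plus an annotation bypass), and diastolic-window extraction.

#' Construct a multichannel phonocardiogram recording
#'
#' @param samples `channels x time` numeric matrix.
#' @param sample_rate sampling rate in Hz (4000 for protocol-conformant runs).
#' @param subject_id subject token.
#' @param condition `"pre"` or `"post"` (or `NA`).
#' @return object of class `pcg_recording`.
#' @export
pcg_recording <- function(samples, sample_rate, subject_id = NA_character_,
                          condition = NA_character_) {
  if (is.vector(samples)) samples <- matrix(samples, nrow = 1)
  stopifnot(is.matrix(samples), sample_rate > 0)
  structure(list(samples = samples, sample_rate = sample_rate,
                 subject_id = subject_id, condition = condition),
            class = "pcg_recording")
}

#' @exportS3Method base::print
print.pcg_recording <- function(x, ...) {
  cat(sprintf("pcg_recording: %d channel(s) x %d samples @ %g Hz (%s, %s)\n",
              nrow(x$samples), ncol(x$samples), x$sample_rate,
              x$subject_id, x$condition))
  invisible(x)
}

#' Read a recording from a multichannel WAV file
#' @param wav_path WAV file path.
#' @param subject_id,condition provenance labels.
#' @return a [pcg_recording].
#' @export
read_recording <- function(wav_path, subject_id = NA_character_,
                           condition = NA_character_) {
  w <- read_wav(wav_path)
  pcg_recording(w$samples, w$sample_rate, subject_id, condition)
}

pcg_signal <- function(samples, sample_rate, applied_delays,
                       subject_id = NA_character_, condition = NA_character_) {
  structure(list(samples = as.numeric(samples), sample_rate = sample_rate,
                 applied_delays = as.integer(applied_delays),
                 subject_id = subject_id, condition = condition),
            class = "pcg_signal")
}

#' @exportS3Method base::print
print.pcg_signal <- function(x, ...) {
  cat(sprintf("pcg_signal: %d samples @ %g Hz, delays (%s)\n",
              length(x$samples), x$sample_rate,
              paste(x$applied_delays, collapse = ", ")))
  invisible(x)
}

#' Delay-and-sum beamforming of a multichannel recording
#'
#' Per-channel delay is estimated as the argmax of cross-correlation with the
#' reference channel within +/- 25 ms, channels are shifted into alignment,
#' truncated to their common support, and averaged. Averaging K channels with
#' independent noise reduces noise power by 1/K (about 6 dB SNR gain at
#' K = 4).
#'
#' @param recording a [pcg_recording] (a single-channel recording is returned
#'   unchanged, making the operation idempotent on its own output).
#' @param reference_channel 1-based index of the reference channel.
#' @param max_lag_s delay search bound in seconds (default 0.025; the
#'   microphones sit on one co-located array, so true delays are
#'   sub-millisecond and the bound guards against locking onto the wrong
#'   beat).
#' @return a `pcg_signal` with `applied_delays` in samples (positive = the
#'   channel lags the reference).
#' @export
beamform <- function(recording, reference_channel = 1L, max_lag_s = 0.025) {
  stopifnot(inherits(recording, "pcg_recording"))
  x <- recording$samples
  fs <- recording$sample_rate
  stop_if_not_finite(x, "recording samples")
  n_ch <- nrow(x)
  if (n_ch == 1) {
    return(pcg_signal(x[1, ], fs, 0L, recording$subject_id,
                      recording$condition))
  }
  if (any(apply(x, 1, function(r) all(r == 0)))) {
    stop("all-zero channel: cross-correlation undefined")
  }
  n <- ncol(x)
  max_lag <- round(max_lag_s * fs)
  ref <- x[reference_channel, ]
  delays <- integer(n_ch)
  for (ch in seq_len(n_ch)) {
    if (ch == reference_channel) { delays[ch] <- 0L; next }
    cc <- xcorr_lagged(ref, x[ch, ], max_lag)
    delays[ch] <- cc$lags[which.max(cc$values)]
  }
  # channel ch satisfies x_ch(t) ~ ref(t - d); aligned_ch(t) = x_ch(t + d)
  lo <- max(0L, -min(delays))   # 0-based start so t + d >= 0 for all channels
  hi <- n - max(0L, max(delays))
  idx0 <- lo:(hi - 1L)          # 0-based common support
  aligned <- vapply(seq_len(n_ch),
                    function(ch) x[ch, idx0 + delays[ch] + 1L],
                    numeric(length(idx0)))
  pcg_signal(rowMeans(aligned), fs, delays, recording$subject_id,
             recording$condition)
}

pcg_segment <- function(samples, start_sample, kind, sample_rate,
                        subject_id = NA_character_,
                        condition = NA_character_) {
  structure(list(samples = as.numeric(samples),
                 start_sample = as.integer(start_sample),
                 kind = kind, sample_rate = sample_rate,
                 subject_id = subject_id, condition = condition),
            class = "pcg_segment")
}

#' @exportS3Method base::print
print.pcg_segment <- function(x, ...) {
  cat(sprintf("pcg_segment (%s): %d samples starting at %d (%s, %s)\n",
              x$kind, length(x$samples), x$start_sample, x$subject_id,
              x$condition))
  invisible(x)
}

#' Sliding full-cycle windows over a beamformed signal
#'
#' Windows of `window_s` seconds with `overlap` fractional overlap (defaults:
#' 1.5 s with 50% overlap, i.e. hop 0.75 s); only fully contained windows are
#' emitted, unaligned and unshifted, with no per-window normalization.
#'
#' @param signal a `pcg_signal`.
#' @param window_s window length in seconds.
#' @param overlap fractional overlap in `[0, 1)`.
#' @return list of `pcg_segment`s (kind `full_cycle_window`), `start_sample`
#'   0-based and increasing by the hop; empty if the signal is shorter than
#'   one window.
#' @export
sliding_windows <- function(signal, window_s = 1.5, overlap = 0.5) {
  stopifnot(inherits(signal, "pcg_signal"), overlap >= 0, overlap < 1)
  fs <- signal$sample_rate
  win <- round(window_s * fs)
  hop <- round(window_s * (1 - overlap) * fs)
  n <- length(signal$samples)
  if (n < win) return(list())
  starts <- seq.int(0L, n - win, by = hop)
  lapply(starts, function(s0) {
    pcg_segment(signal$samples[(s0 + 1L):(s0 + win)], s0, "full_cycle_window",
                fs, signal$subject_id, signal$condition)
  })
}

#' Detect S2 onsets with a simplified envelope detector
#'
#' Detector: band-limit to the valve-transient range (20-90 Hz, which
#' suppresses higher-frequency murmur energy) -> homomorphic envelope
#' (Gaussian low-pass of log-energy) -> peak picking with a minimum
#' inter-peak distance of 0.2 s -> peaks paired so the shorter intra-pair
#' gap is systole, labelling the second (lower-energy) transient of each
#' pair S2 -> physiological rate gate of 40-180 bpm on the S2 train. This
#' replaces full HSMM heart-sound segmentation; exact onsets can always be
#' injected through `annotations`.
#'
#' @param signal a `pcg_signal` of at least 2 s.
#' @param annotations optional bypass: either a numeric vector of S2 onset
#'   sample indices or a CSV path with column `s2_onset_sample`; returned
#'   verbatim.
#' @return strictly increasing 0-based S2 onset indices (possibly empty, with
#'   a warning, when no credible transients are found).
#' @export
detect_s2 <- function(signal, annotations = NULL) {
  if (!is.null(annotations)) {
    if (is.character(annotations)) {
      annotations <- utils::read.csv(annotations)$s2_onset_sample
    }
    return(as.integer(annotations))
  }
  stopifnot(inherits(signal, "pcg_signal"))
  fs <- signal$sample_rate
  x <- signal$samples
  if (length(x) < 2 * fs) stop("need at least 2 s of signal for S2 detection")

  xb <- sos_filtfilt(butter_bandpass(2, 20, 90, fs), x)
  # log-energy with a relative noise floor (keeps short transients visible
  # after smoothing), low-passed by a 20 ms Gaussian
  env <- exp(gauss_smooth(log(xb^2 + 0.01 * max(xb^2)), sigma = 0.02 * fs))
  if (max(env) < 6 * stats::median(env)) {
    warning("no credible heart-sound transients found")
    return(integer(0))
  }
  # local maxima, greedy by height with 0.2 s minimum separation
  n <- length(env)
  cand <- which(env[2:(n - 1)] > env[1:(n - 2)] &
                env[2:(n - 1)] >= env[3:n]) + 1L
  cand <- cand[env[cand] >= 0.2 * max(env)]
  cand <- cand[order(-env[cand])]
  min_dist <- round(0.2 * fs)
  peaks <- integer(0)
  for (p in cand) {
    if (!length(peaks) || all(abs(peaks - p) >= min_dist)) {
      peaks <- c(peaks, p)
    }
  }
  peaks <- sort(peaks)
  if (length(peaks) < 2) {
    warning("fewer than two envelope peaks; no S2 onsets")
    return(integer(0))
  }
  # pair alternating peaks: systole (S1->S2) is the shorter intra-pair gap
  gaps <- diff(peaks)
  mean_gap <- function(offset) {
    i <- seq.int(1L + offset, length(gaps), by = 2L)
    if (!length(i)) Inf else mean(gaps[i])
  }
  offset <- if (mean_gap(0L) <= mean_gap(1L)) 0L else 1L
  first <- seq.int(1L + offset, length(peaks) - 1L, by = 2L)
  s2 <- peaks[first + 1L]
  # physiological rate gate on the S2 train: 40-180 bpm
  lo <- 60 / 180 * fs
  hi <- 60 / 40 * fs
  repeat {
    if (length(s2) < 2) break
    iv <- diff(s2)
    bad <- which(iv < lo)
    if (!length(bad)) break
    b <- bad[1]
    drop <- if (env[s2[b]] < env[s2[b + 1]]) b else b + 1L
    s2 <- s2[-drop]
  }
  if (length(s2) >= 2 && any(diff(s2) > hi)) {
    # gaps longer than the slowest plausible beat mean missed beats, not an
    # error; onsets are kept (downstream windows simply skip the gap)
  }
  as.integer(s2 - 1L)  # 0-based
}

#' Extract diastolic windows from S2 onsets
#'
#' For each S2 onset `o`, the diastolic window is the samples
#' `[o + round(0.100 * fs), o + round(0.100 * fs) + round(0.128 * fs))` --
#' the first 128 ms of audio beginning 100 ms after the S2 onset (at 4000 Hz:
#' 512 samples starting 400 samples after `o`). Windows running past the
#' signal end are dropped.
#'
#' @param signal a `pcg_signal`.
#' @param s2_onsets 0-based onset indices.
#' @param offset_s,length_s window placement parameters (defaults 0.100 and
#'   0.128 seconds).
#' @return list of `pcg_segment`s of kind `diastolic_window`.
#' @export
extract_diastolic_windows <- function(signal, s2_onsets, offset_s = 0.100,
                                      length_s = 0.128) {
  stopifnot(inherits(signal, "pcg_signal"))
  fs <- signal$sample_rate
  off <- round(offset_s * fs)
  len <- round(length_s * fs)
  n <- length(signal$samples)
  out <- list()
  for (o in s2_onsets) {
    s0 <- o + off                       # 0-based start
    if (s0 + len > n) next              # drop at signal end
    out[[length(out) + 1L]] <- pcg_segment(
      signal$samples[(s0 + 1L):(s0 + len)], s0, "diastolic_window", fs,
      signal$subject_id, signal$condition)
  }
  out
}
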