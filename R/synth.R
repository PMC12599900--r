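# Synthetic multichannel phonocardiogram generator with planted, controllable
# occlusion-murmur structure. Every downstream stage of the pipeline is
# testable against this generator's ground truth without patient data.

#' Configuration for the synthetic phonocardiogram generator
#'
#' Defaults mirror the recording protocol the pipeline targets: 15-second,
#' 4-channel recordings at 4000 Hz, one pre- and one post-intervention
#' recording per subject. The murmur is band-limited diastolic turbulence;
#' its level is set relative to the S1/S2 transient power.
#'
#' @param sample_rate sampling rate in Hz (default 4000).
#' @param duration recording length in seconds (default 15).
#' @param n_channels number of microphone channels (default 4).
#' @param heart_rate beats per minute (default 60).
#' @param s1_s2_interval S1-to-S2 spacing in seconds (default 0.30).
#' @param murmur_band `c(low, high)` murmur pass band in Hz (default
#'   `c(150, 400)`, the high-frequency part of the 65-400 Hz analysis band
#'   where occlusion turbulence concentrates).
#' @param murmur_snr_db murmur power in dB relative to the S1/S2 transient
#'   power (default 0 = equal power inside its support).
#' @param channel_delays integer per-channel delays in samples (default
#'   `c(0, 1, 2, 3)`: co-located array, sub-millisecond true delays).
#' @param noise_snr_db additive white-noise level per channel, in dB below
#'   the heart-sound template power (default 20).
#' @param post_murmur_gain linear murmur amplitude factor for the
#'   post-intervention condition (default 0: treatment removes the murmur;
#'   expose values in `(0, 1)` for graded experiments).
#' @param seed integer RNG seed.
#' @return object of class `synth_config`.
#' @export
synth_config <- function(sample_rate = 4000, duration = 15, n_channels = 4L,
                         heart_rate = 60, s1_s2_interval = 0.30,
                         murmur_band = c(150, 400), murmur_snr_db = 0,
                         channel_delays = c(0L, 1L, 2L, 3L),
                         noise_snr_db = 20, post_murmur_gain = 0,
                         seed = 1L) {
  stopifnot(sample_rate > 0, duration > 0, n_channels >= 1,
            heart_rate > 0, s1_s2_interval > 0,
            length(murmur_band) == 2, murmur_band[1] > 0,
            murmur_band[2] > murmur_band[1],
            murmur_band[2] < sample_rate / 2,
            length(channel_delays) == n_channels,
            post_murmur_gain >= 0)
  structure(list(sample_rate = sample_rate, duration = duration,
                 n_channels = as.integer(n_channels), heart_rate = heart_rate,
                 s1_s2_interval = s1_s2_interval, murmur_band = murmur_band,
                 murmur_snr_db = murmur_snr_db,
                 channel_delays = as.integer(channel_delays),
                 noise_snr_db = noise_snr_db,
                 post_murmur_gain = post_murmur_gain,
                 seed = as.integer(seed)),
            class = "synth_config")
}

# Gaussian-windowed sinusoid transient added in place at center index `at`.
add_transient <- function(x, at, freq, sigma_s, amp, fs) {
  r <- ceiling(3.5 * sigma_s * fs)
  t <- (at - r):(at + r)
  keep <- t >= 1 & t <= length(x)
  t <- t[keep]
  tau <- (t - at) / fs
  x[t] <- x[t] + amp * exp(-tau^2 / (2 * sigma_s^2)) * cos(2 * pi * freq * tau)
  x
}

#' Generate one synthetic multichannel recording with ground truth
#'
#' The mono template is a train of S1/S2 transients (Gaussian-windowed
#' sinusoids; S1 ~35 Hz, S2 ~50 Hz centers) at the configured heart rate.
#' For `condition = "pre"` (and for `post` when `post_murmur_gain > 0`),
#' band-pass-filtered white noise is added inside each diastolic interval at
#' `murmur_snr_db` relative to the transient power. Each channel is the
#' template shifted by its configured integer delay plus independent white
#' noise at `noise_snr_db`. Identical `(config, condition)` always produces
#' bit-identical output.
#'
#' @param config a [synth_config()].
#' @param condition `"pre"` or `"post"`.
#' @return list with `recording` (a [pcg_recording]) and `truth` (class
#'   `synth_truth`: `s1_onsets`, `s2_onsets` as 0-based sample indices of the
#'   transient centers, `murmur_support` as a two-column 0-based
#'   `[start, end)` matrix, and `condition`).
#' @export
generate_recording <- function(config, condition = c("pre", "post")) {
  condition <- match.arg(condition)
  stopifnot(inherits(config, "synth_config"))
  fs <- config$sample_rate
  n <- round(config$duration * fs)
  if (any(abs(config$channel_delays) > 0.1 * n)) {
    stop("channel delay magnitude exceeds 10% of the signal length")
  }
  with_seed(derive_seed(config$seed, if (condition == "pre") 1L else 2L), {
    period <- 60 / config$heart_rate
    s2_pad <- 0.05  # keep the last S2 transient fully inside the recording
    beat_t <- seq(0.5, config$duration - config$s1_s2_interval - s2_pad,
                  by = period)
    s1_amp <- 1.0 * stats::runif(length(beat_t), 0.95, 1.05)
    s2_amp <- 0.7 * stats::runif(length(beat_t), 0.95, 1.05)

    template <- numeric(n)
    s1_idx <- as.integer(round(beat_t * fs)) + 1L   # 1-based internally
    s2_idx <- as.integer(round((beat_t + config$s1_s2_interval) * fs)) + 1L
    for (k in seq_along(beat_t)) {
      template <- add_transient(template, s1_idx[k], 35, 0.012, s1_amp[k], fs)
      template <- add_transient(template, s2_idx[k], 50, 0.010, s2_amp[k], fs)
    }
    # transient power: template power over transient supports
    support <- abs(template) > 1e-4
    p_heart <- mean(template[support]^2)

    murmur_gain <- if (condition == "pre") 1 else config$post_murmur_gain
    murmur_support <- matrix(integer(0), ncol = 2)
    if (murmur_gain > 0) {
      sos <- butter_bandpass(3, config$murmur_band[1], config$murmur_band[2], fs)
      p_target <- p_heart * 10^(config$murmur_snr_db / 10) * murmur_gain^2
      supports <- list()
      for (k in seq_along(beat_t)) {
        m_start <- s2_idx[k] + round(0.100 * fs)
        m_end <- if (k < length(beat_t)) s1_idx[k + 1] - round(0.020 * fs)
                 else min(n, m_start + round(0.4 * period * fs))
        if (m_end - m_start < round(0.05 * fs) || m_end > n) next
        len <- m_end - m_start + 1L
        burst <- sos_filter(sos, stats::rnorm(len + 200))[-(1:200)]
        ramp <- round(0.010 * fs)
        env <- c(hann_window(2 * ramp)[1:ramp], rep(1, len - 2 * ramp),
                 rev(hann_window(2 * ramp)[1:ramp]))
        burst <- burst * env
        burst <- burst * sqrt(p_target / mean(burst^2))
        template[m_start:m_end] <- template[m_start:m_end] + burst
        supports[[length(supports) + 1L]] <- c(m_start - 1L, m_end)  # 0-based [start, end)
      }
      if (length(supports)) murmur_support <- do.call(rbind, supports)
    }

    p_template <- mean(template^2)
    noise_sd <- sqrt(p_template * 10^(-config$noise_snr_db / 10))
    samples <- matrix(0, nrow = config$n_channels, ncol = n)
    for (ch in seq_len(config$n_channels)) {
      d <- config$channel_delays[ch]
      shifted <- numeric(n)
      if (d >= 0) {
        shifted[(1 + d):n] <- template[1:(n - d)]
      } else {
        shifted[1:(n + d)] <- template[(1 - d):n]
      }
      samples[ch, ] <- shifted + stats::rnorm(n, sd = noise_sd)
    }

    truth <- structure(list(s1_onsets = s1_idx - 1L, s2_onsets = s2_idx - 1L,
                            murmur_support = murmur_support,
                            condition = condition),
                       class = "synth_truth")
    rec <- pcg_recording(samples, fs, subject_id = NA_character_,
                         condition = condition)
    list(recording = rec, truth = truth)
  })
}

#' Write a set of synthetic subject fixtures to disk
#'
#' Writes `2 * n_subjects` multichannel WAV files (pre and post per subject,
#' 16-bit PCM after peak normalization to 0.9 full scale), one ground-truth
#' CSV sidecar per recording, and a manifest CSV. Subject-specific sub-seeds
#' derive deterministically from `config$seed`.
#'
#' @param config a [synth_config()]; per-subject seeds are derived from its
#'   `seed`.
#' @param n_subjects number of subjects (default 12).
#' @param out_dir output directory (created if needed).
#' @param force overwrite an existing manifest (default `FALSE`).
#' @return the manifest as a data frame (columns `subject_id`, `condition`,
#'   `wav_path`, `truth_path`), invisibly also written to
#'   `file.path(out_dir, "manifest.csv")`.
#' @export
write_fixture_set <- function(config, n_subjects = 12L, out_dir,
                              force = FALSE) {
  stopifnot(n_subjects >= 1)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest_path <- file.path(out_dir, "manifest.csv")
  if (file.exists(manifest_path) && !force) {
    stop("manifest already exists at ", manifest_path, " (use force = TRUE)")
  }
  rows <- list()
  for (s in seq_len(n_subjects)) {
    for (condition in c("pre", "post")) {
      cfg <- config
      cfg$seed <- derive_seed(config$seed, 100L + s,
                              if (condition == "pre") 1L else 2L)
      gen <- generate_recording(cfg, condition)
      sid <- sprintf("S%02d", s)
      wav_path <- file.path(out_dir, sprintf("%s_%s.wav", sid, condition))
      truth_path <- file.path(out_dir, sprintf("%s_%s_truth.csv", sid, condition))
      x <- gen$recording$samples
      peak <- max(abs(x))
      if (peak > 0) x <- x * (0.9 / peak)
      write_wav(x, cfg$sample_rate, wav_path)
      write_ground_truth(gen$truth, truth_path)
      rows[[length(rows) + 1L]] <- data.frame(
        subject_id = sid, condition = condition,
        wav_path = basename(wav_path), truth_path = basename(truth_path),
        stringsAsFactors = FALSE)
    }
  }
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, manifest_path, row.names = FALSE)
  # paths are stored relative in the CSV; return them resolved
  manifest$wav_path <- file.path(out_dir, manifest$wav_path)
  manifest$truth_path <- file.path(out_dir, manifest$truth_path)
  manifest
}

# Ground-truth sidecar: event_type, start_sample, end_sample (0-based,
# half-open; point events have end = start + 1).
write_ground_truth <- function(truth, path) {
  df <- rbind(
    data.frame(event_type = "s1", start_sample = truth$s1_onsets,
               end_sample = truth$s1_onsets + 1L),
    data.frame(event_type = "s2", start_sample = truth$s2_onsets,
               end_sample = truth$s2_onsets + 1L),
    if (nrow(truth$murmur_support)) {
      data.frame(event_type = "murmur",
                 start_sample = truth$murmur_support[, 1],
                 end_sample = truth$murmur_support[, 2])
    })
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a ground-truth sidecar CSV
#' @param path sidecar written by [write_fixture_set()].
#' @return `synth_truth` list.
#' @export
read_ground_truth <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  m <- df[df$event_type == "murmur", , drop = FALSE]
  structure(list(
    s1_onsets = as.integer(df$start_sample[df$event_type == "s1"]),
    s2_onsets = as.integer(df$start_sample[df$event_type == "s2"]),
    murmur_support = cbind(as.integer(m$start_sample),
                           as.integer(m$end_sample)),
    condition = NA_character_), class = "synth_truth")
}

#' Read a fixture-set manifest
#' @param out_dir directory holding `manifest.csv`.
#' @return manifest data frame with absolute paths resolved.
#' @export
read_manifest <- function(out_dir) {
  manifest <- utils::read.csv(file.path(out_dir, "manifest.csv"),
                              stringsAsFactors = FALSE)
  manifest$wav_path <- file.path(out_dir, manifest$wav_path)
  manifest$truth_path <- file.path(out_dir, manifest$truth_path)
  manifest
}
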