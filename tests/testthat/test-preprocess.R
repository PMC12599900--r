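test_that("beamforming identical channels returns the channel unchanged", {
  x <- sin(2 * pi * 40 * (0:7999) / 4000)
  rec <- pcg_recording(rbind(x, x, x, x), 4000)
  bf <- beamform(rec)
  expect_identical(bf$applied_delays, rep(0L, 4))
  expect_lt(max(abs(bf$samples - x)), 1e-12)
})

test_that("beamforming recovers planted integer delays", {
  cfg <- synth_config(duration = 4, channel_delays = c(0L, 3L, -2L, 5L),
                      noise_snr_db = 20, seed = 2)
  g <- generate_recording(cfg, "pre")
  bf <- beamform(g$recording)
  expect_identical(bf$applied_delays, c(0L, 3L, -2L, 5L))
})

test_that("beamforming is idempotent on a single-channel signal", {
  x <- stats::rnorm(4000)
  rec <- pcg_recording(matrix(x, 1), 4000)
  bf <- beamform(rec)
  expect_identical(bf$samples, x)
})

test_that("all-zero channels are rejected", {
  rec <- pcg_recording(rbind(stats::rnorm(4000), 0), 4000)
  expect_error(beamform(rec), "all-zero")
})

test_that("sliding windows follow the 1.5 s / 50% overlap contract", {
  mk <- function(n) pcg_signal(stats::rnorm(n), 4000, 0L)
  w <- sliding_windows(mk(60000))          # 15 s at 4000 Hz
  expect_length(w, 19)
  expect_true(all(vapply(w, function(s) length(s$samples), integer(1)) ==
                    6000L))
  starts <- vapply(w, `[[`, integer(1), "start_sample")
  expect_identical(starts, seq(0L, by = 3000L, length.out = 19))
  expect_length(sliding_windows(mk(6000)), 1)    # exactly one window
  expect_length(sliding_windows(mk(5960)), 0)    # 1.49 s -> none
})

test_that("even-indexed windows reassemble the signal prefix losslessly", {
  sig <- pcg_signal(stats::rnorm(60000), 4000, 0L)
  w <- sliding_windows(sig)
  even <- w[seq(1, length(w), by = 2)]
  recon <- unlist(lapply(even, `[[`, "samples"))
  expect_identical(recon, sig$samples[seq_along(recon)])
})

test_that("S2 detection finds planted onsets at high SNR", {
  cfg <- synth_config(duration = 10, noise_snr_db = 20, seed = 4)
  g <- generate_recording(cfg, "post")
  bf <- beamform(g$recording)
  s2 <- detect_s2(bf)
  truth <- g$truth$s2_onsets
  expect_true(abs(length(s2) - length(truth)) <= 1)
  tol <- round(0.020 * 4000)
  matched <- vapply(s2, function(o) min(abs(truth - o)) <= tol, logical(1))
  expect_true(all(matched))
})

test_that("S2 detection recall and precision exceed 0.9 over seeds", {
  tol <- round(0.020 * 4000)
  stats_per_seed <- vapply(1:10, function(seed) {
    cfg <- synth_config(duration = 6, noise_snr_db = 15, seed = seed)
    g <- generate_recording(cfg, "pre")
    s2 <- detect_s2(beamform(g$recording))
    truth <- g$truth$s2_onsets
    hit <- vapply(truth, function(o) any(abs(s2 - o) <= tol), logical(1))
    used <- vapply(s2, function(o) any(abs(truth - o) <= tol), logical(1))
    c(recall = mean(hit), precision = if (length(s2)) mean(used) else 0)
  }, numeric(2))
  expect_gte(mean(stats_per_seed["recall", ]), 0.9)
  expect_gte(mean(stats_per_seed["precision", ]), 0.9)
})

test_that("white noise yields no credible S2 onsets", {
  sig <- pcg_signal(with_seed(8, stats::rnorm(20000)), 4000, 0L)
  expect_warning(s2 <- detect_s2(sig), "transient|peak")
  expect_length(s2, 0)
})

test_that("annotation bypass returns onsets verbatim", {
  sig <- pcg_signal(stats::rnorm(20000), 4000, 0L)
  ann <- c(1000L, 5000L, 9000L)
  expect_identical(detect_s2(sig, annotations = ann), ann)
  p <- tempfile(fileext = ".csv")
  utils::write.csv(data.frame(s2_onset_sample = ann), p, row.names = FALSE)
  expect_identical(detect_s2(sig, annotations = p), ann)
})

test_that("diastolic windows start 100 ms after S2 and last 128 ms", {
  x <- seq_len(12000) - 1    # sample i holds value i
  sig <- pcg_signal(x, 4000, 0L)
  dw <- extract_diastolic_windows(sig, c(4000L))
  expect_length(dw, 1)
  expect_identical(dw[[1]]$start_sample, 4400L)
  expect_length(dw[[1]]$samples, 512L)
  expect_identical(dw[[1]]$samples, as.numeric(4400:4911))  # [4400, 4912)
  # onset too close to the end is dropped
  expect_length(extract_diastolic_windows(sig, c(12000L - 100L)), 0)
  # count check
  dw15 <- extract_diastolic_windows(pcg_signal(numeric(60000), 4000, 0L),
                                    seq(0L, by = 4000L, length.out = 15))
  expect_length(dw15, 15)
  expect_true(all(vapply(dw15, function(s) length(s$samples),
                         integer(1)) == 512L))
})

test_that("averaging four delayed noisy copies gains about 6 dB SNR", {
  gains <- vapply(1:10, function(seed) {
    clean <- generate_recording(
      synth_config(duration = 4, n_channels = 1, channel_delays = 0L,
                   noise_snr_db = 200, seed = seed), "post")
    template <- clean$recording$samples[1, ]
    n <- length(template)
    delays <- c(0L, 3L, -2L, 5L)
    p_sig <- mean(template^2)
    noise_sd <- sqrt(p_sig * 10^(-20 / 10))   # 20 dB SNR per channel
    x <- with_seed(seed + 1000, {
      t(vapply(delays, function(d) {
        shifted <- numeric(n)
        if (d >= 0) shifted[(1 + d):n] <- template[1:(n - d)]
        else shifted[1:(n + d)] <- template[(1 - d):n]
        shifted + stats::rnorm(n, sd = noise_sd)
      }, numeric(n)))
    })
    bf <- beamform(pcg_recording(x, 4000))
    m <- length(bf$samples)
    start <- max(0L, -min(bf$applied_delays))   # common-support offset
    noise_out <- bf$samples - template[start + seq_len(m)]
    10 * log10(noise_sd^2 / mean(noise_out^2))
  }, numeric(1))
  expect_lt(abs(mean(gains) - 6.0), 0.5)
})
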