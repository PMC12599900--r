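fake_decomposition <- function(atoms, subject = "S01", condition = "pre",
                               kind = "diastolic_window", start = 0L,
                               length = 512L) {
  atoms$frequency_hz <- atoms$frequency_hz %||%
    sample(c(0, 125, 250, 500), nrow(atoms), replace = TRUE)
  atoms$phase <- atoms$phase %||% stats::runif(nrow(atoms), -pi, pi)
  atoms$coefficient_magnitude <- atoms$coefficient_magnitude %||%
    stats::runif(nrow(atoms), 0.1, 3)
  pcgatoms:::new_decomposition(
    atoms, residual_energy = 0.1, residual_energies = numeric(0),
    initial_energy = 1, length = length, fs = 4000,
    segment_ref = list(subject_id = subject, condition = condition,
                       kind = kind, start_sample = start))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("influence counts follow the worked two-atom example", {
  one <- data.frame(iteration = 0L, octave = 5L, translation = 100L)
  expect_identical(unlist(influence_features(one)),
                   c(influence_given = 0L, influence_received = 0L,
                     low_octave_influence = 0L, high_octave_influence = 0L))
  two <- data.frame(iteration = c(0L, 1L), octave = c(4L, 6L),
                    translation = c(200L, 200L))
  inf <- influence_features(two)
  expect_identical(inf$influence_given, c(1L, 0L))
  expect_identical(inf$influence_received, c(0L, 1L))
  expect_identical(inf$low_octave_influence, c(0L, 1L))
  expect_identical(inf$high_octave_influence, c(1L, 0L))
})

test_that("influence counts match the brute-force oracle", {
  with_seed(11, {
    for (rep in 1:10) {
      atoms <- random_atom_table(sample(5:60, 1))
      expect_identical(influence_features(atoms), naive_influence(atoms))
    }
  })
})

test_that("influence given/received pair up over a decomposition", {
  with_seed(12, {
    atoms <- random_atom_table(100)
    inf <- influence_features(atoms)
    expect_identical(sum(inf$influence_given), sum(inf$influence_received))
    # given + received = total overlap partners
    du <- abs(outer(atoms$translation, atoms$translation, "-"))
    th <- outer(2^atoms$octave, 2^atoms$octave, "+") / 2
    ov <- du < th; diag(ov) <- FALSE
    expect_identical(inf$influence_given + inf$influence_received,
                     as.integer(rowSums(ov)))
  })
})

test_that("feature scaling matches the documented ranges", {
  sc <- structure(list(magnitude_mean = 1, magnitude_sd = 2,
                       freq_bounds = c(0, 1000), octave_bounds = c(2, 12),
                       patient_levels = c("S01", "S02")),
                  class = "atom_scaler")
  raw <- data.frame(coefficient_magnitude = c(1, 3),
                    phase = c(pi / 2, -pi),
                    frequency = c(1000, 0), octave = c(12, 2),
                    influence_given = c(3L, 0L),
                    influence_received = c(0L, 1L),
                    low_octave_influence = c(2L, 0L),
                    high_octave_influence = c(0L, 5L))
  out <- scale_features(raw, sc, "S02")
  f <- out$features
  expect_identical(out$patient_code, 2L)
  expect_equal(f[, "frequency"], c(1, 0))
  expect_equal(f[, "octave"], c(1, 0))
  expect_equal(f[, "coefficient_magnitude"], c(0, 1))
  expect_equal(f[1, c("phase_sin", "phase_cos")],
               c(phase_sin = 1, phase_cos = 0), tolerance = 1e-12)
  # phase is circular: -pi and pi map to the same components
  raw2 <- raw; raw2$phase <- c(pi / 2, pi)
  f2 <- scale_features(raw2, sc, "S02")$features
  expect_equal(f2[2, c("phase_sin", "phase_cos")],
               f[2, c("phase_sin", "phase_cos")], tolerance = 1e-12)
  expect_true(all(abs(f[, "phase_sin"]^2 + f[, "phase_cos"]^2 - 1) < 1e-9))
  # influence counts pass through
  expect_equal(f[, "influence_given"], raw$influence_given)
  # unseen patient is an explicit error
  expect_error(scale_features(raw, sc, "S99"), "unseen patient")
  # magnitude / frequency / octave scalings invert exactly
  inv <- pcgatoms:::unscale_features(f, sc)
  expect_equal(inv$coefficient_magnitude, raw$coefficient_magnitude,
               tolerance = 1e-9)
  expect_equal(inv$frequency, raw$frequency, tolerance = 1e-9)
  expect_equal(inv$octave, raw$octave, tolerance = 1e-9)
})

test_that("scaler state round-trips through JSON", {
  sc <- structure(list(magnitude_mean = 0.5, magnitude_sd = 1.5,
                       freq_bounds = c(0, 1000), octave_bounds = c(2, 12),
                       patient_levels = c("S01", "S02", "S03")),
                  class = "atom_scaler")
  p <- tempfile(fileext = ".json")
  scaler_to_json(sc, p)
  sc2 <- scaler_from_json(p)
  expect_equal(sc2$magnitude_mean, sc$magnitude_mean)
  expect_identical(sc2$patient_levels, sc$patient_levels)
})

test_that("sample assembly yields one record per segment", {
  with_seed(13, {
    decomps <- list()
    for (s in sprintf("S%02d", 1:12)) {
      for (cond in c("pre", "post")) {
        for (w in 1:19) {
          decomps[[length(decomps) + 1]] <- fake_decomposition(
            random_atom_table(10), subject = s, condition = cond,
            kind = "full_cycle_window", start = (w - 1L) * 3000L,
            length = 6000L)
        }
      }
    }
    samples <- assemble_samples(decomps)
    expect_length(samples, 456)      # 12 subjects x 2 conditions x 19
    scaler <- fit_scaler(samples)
    scaled <- apply_scaler(samples, scaler, include_patient_id = FALSE)
    expect_identical(ncol(scaled[[1]]$features), 9L)
    expect_identical(colnames(scaled[[1]]$features),
                     c("coefficient_magnitude", "phase_sin", "phase_cos",
                       "frequency", "octave", "influence_given",
                       "influence_received", "low_octave_influence",
                       "high_octave_influence"))
    scaled10 <- apply_scaler(samples, scaler, include_patient_id = TRUE)
    expect_identical(ncol(scaled10[[1]]$features), 10L)
    expect_identical(scaled10[[1]]$label, 0L)  # pre = 0
    expect_identical(scaled10[[20]]$label, 1L) # post = 1
  })
})

test_that("zero-atom decompositions are skipped with a warning", {
  with_seed(14, {
    d_ok <- fake_decomposition(random_atom_table(5))
    d_empty <- fake_decomposition(random_atom_table(1)[0, ])
    expect_warning(samples <- assemble_samples(list(d_ok, d_empty)),
                   "zero atoms")
    expect_length(samples, 1)
  })
})
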