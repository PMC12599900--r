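# Shared fixtures, built programmatically and memoized across test files.
# Scale note: acceptance fixtures are scaled down from the 15 s / 100-atom
# protocol defaults (6 s recordings, 60 atoms per diastolic window) so the
# full suite stays inside its CPU budget; the properties under test do not
# depend on these sizes.

if (!exists(".pcg_fixture_cache", envir = globalenv())) {
  assign(".pcg_fixture_cache", new.env(parent = emptyenv()),
         envir = globalenv())
}
.fixcache <- get(".pcg_fixture_cache", envir = globalenv())

fixture_memo <- function(key, builder) {
  if (is.null(.fixcache[[key]])) .fixcache[[key]] <- builder()
  .fixcache[[key]]
}

# Synthetic cohort -> diastolic windows -> decompositions -> scaled samples.
build_cohort <- function(seed, n_subjects, duration = 6, murmur_snr_db = 0,
                         n_atoms = 60L, post_murmur_gain = 0) {
  scfg <- synth_config(duration = duration, murmur_snr_db = murmur_snr_db,
                       noise_snr_db = 20, post_murmur_gain = post_murmur_gain,
                       seed = derive_seed(seed, 1L))
  dirn <- file.path(tempfile("cohort"), "fixtures")
  man <- write_fixture_set(scfg, n_subjects, dirn, force = TRUE)
  segs <- list()
  s2_tab <- list()
  for (i in seq_len(nrow(man))) {
    rec <- read_recording(man$wav_path[i], man$subject_id[i],
                          man$condition[i])
    sig <- beamform(rec)
    s2 <- detect_s2(sig)
    segs <- c(segs, extract_diastolic_windows(sig, s2))
    s2_tab[[i]] <- data.frame(subject_id = man$subject_id[i],
                              condition = man$condition[i],
                              s2_onset_sample = s2,
                              recording_length = length(sig$samples))
  }
  dict <- build_dictionary(512L, c(2L, 12L), 1000, 4000)
  decomps <- lapply(segs, decompose, n_atoms = n_atoms, dictionary = dict)
  samples <- assemble_samples(decomps)
  splits <- split_dataset(samples,
                          split_spec(seed = derive_seed(seed, 2L)))
  scaler <- fit_scaler(samples[splits$train])
  samples <- apply_scaler(samples, scaler)
  list(manifest = man, segments = segs, decomps = decomps,
       samples = samples, splits = splits, scaler = scaler,
       s2 = do.call(rbind, s2_tab), fixture_dir = dirn)
}

# The 12-subject corpus used by the end-to-end acceptance criteria
# (50 atoms per 512-sample diastolic window, scaled from the 100-atom
# protocol default for the CPU budget).
acceptance_corpus <- function() {
  fixture_memo("corpus12", function() build_cohort(101L, 12L, n_atoms = 50L))
}

# The 25-trial hyperparameter search on the corpus (shared by several
# acceptance checks).
acceptance_search <- function() {
  fixture_memo("search25", function() {
    co <- acceptance_corpus()
    hyperparameter_search(co$samples, co$splits, n_trials = 25L,
                          seed = derive_seed(101L, 3L),
                          max_epochs = 25L, patience = 5L)
  })
}

# Separable toy set samples: "pre" sets contain a block of strong
# high-frequency atoms, "post" sets do not.
make_toy_samples <- function(n_per_class = 30, seed = 5, bump = 3,
                             n_features = 9) {
  with_seed(seed, {
    samples <- list()
    for (lab in 0:1) {
      for (i in seq_len(n_per_class)) {
        k <- sample(10:20, 1)
        f <- matrix(stats::rnorm(k * n_features, sd = 0.3), k, n_features)
        colnames(f) <- c("coefficient_magnitude", "phase_sin", "phase_cos",
                         "frequency", "octave", "influence_given",
                         "influence_received", "low_octave_influence",
                         "high_octave_influence")[seq_len(n_features)]
        if (lab == 0L) {
          f[1:5, 4] <- f[1:5, 4] + bump   # frequency block
          f[1:5, 1] <- f[1:5, 1] + bump   # magnitude block
        }
        samples[[length(samples) + 1]] <- list(
          features = f, label = lab,
          subject_id = sprintf("S%02d", (i %% 4) + 1),
          segment_kind = "toy", start_sample = 0L,
          decomposition_index = length(samples) + 1L)
      }
    }
    samples
  })
}

# Random variable-cardinality batch for model-level tests.
random_batch <- function(n_samples, dim = 9, min_atoms = 2, max_atoms = 20,
                         seed = 1) {
  with_seed(seed, {
    ns <- sample(min_atoms:max_atoms, n_samples, replace = TRUE)
    X <- matrix(stats::rnorm(sum(ns) * dim), ncol = dim)
    list(X = X, sid = rep(seq_len(n_samples), ns),
         y = sample(0:1, n_samples, replace = TRUE), n = n_samples)
  })
}
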