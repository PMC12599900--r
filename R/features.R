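# Per-atom features and scaling. Nine model features per atom: scaled
# coefficient magnitude, phase sine and cosine, scaled frequency and octave,
# and four atomic-influence counts; the encoded patient ID is appended as an
# optional extra model input. The absolute translation is deliberately NOT a
# model feature (it stays in the decomposition for reconstruction); the
# influence counts inject relative temporal structure instead.

#' Atomic-influence counts for one decomposition
#'
#' Two atoms `a`, `b` overlap iff `|u_a - u_b| < (2^j_a + 2^j_b) / 2`, i.e.
#' their envelope scales touch. For each atom (excluding itself):
#' `influence_given` counts overlapping atoms extracted later,
#' `influence_received` counts overlapping atoms extracted earlier, and
#' `low_octave_influence` / `high_octave_influence` count overlapping atoms
#' of strictly lower / higher octave. The given/received split keyed to
#' extraction order reflects matching pursuit's energy-ordered semantics.
#'
#' @param decomposition a [decompose()] result (or any data frame with
#'   `octave`, `translation`, `iteration` columns).
#' @return data frame with columns `influence_given`, `influence_received`,
#'   `low_octave_influence`, `high_octave_influence` (one row per atom).
#' @export
influence_features <- function(decomposition) {
  u <- decomposition$translation
  j <- decomposition$octave
  it <- decomposition$iteration
  n <- length(u)
  if (n == 0) {
    return(data.frame(influence_given = integer(0),
                      influence_received = integer(0),
                      low_octave_influence = integer(0),
                      high_octave_influence = integer(0)))
  }
  du <- abs(outer(u, u, "-"))
  thresh <- outer(2^j, 2^j, "+") / 2
  ov <- du < thresh
  diag(ov) <- FALSE
  later <- outer(it, it, function(a, b) b > a)
  lower <- outer(j, j, function(a, b) b < a)
  higher <- outer(j, j, function(a, b) b > a)
  data.frame(
    influence_given = as.integer(rowSums(ov & later)),
    influence_received = as.integer(rowSums(ov & !later)),
    low_octave_influence = as.integer(rowSums(ov & lower)),
    high_octave_influence = as.integer(rowSums(ov & higher)))
}

# Raw (unscaled) per-atom feature table for one decomposition.
raw_atom_features <- function(decomposition) {
  inf <- influence_features(decomposition)
  cbind(data.frame(coefficient_magnitude = decomposition$coefficient_magnitude,
                   phase = decomposition$phase,
                   frequency = decomposition$frequency_hz,
                   octave = decomposition$octave),
        inf)
}

#' Fit the feature scaler on a training corpus
#'
#' Magnitude gets a standard scaler (moments from the fit corpus only, so the
#' test split never leaks into scaling); frequency and octave use fixed
#' min-max bounds (`[0, 1000]` Hz and octaves `[2, 12]`), which keeps the
#' transform deployment-stable; phase is decomposed into `(sin, cos)`;
#' influence counts pass through unscaled; patient IDs get a persisted
#' integer label map.
#'
#' @param samples list of sample records from [assemble_samples()] restricted
#'   to the training split.
#' @return object of class `atom_scaler` (serializable with
#'   [scaler_to_json()]).
#' @export
fit_scaler <- function(samples) {
  mags <- unlist(lapply(samples, function(s) s$raw$coefficient_magnitude))
  subjects <- sort(unique(vapply(samples, function(s) s$subject_id, character(1))))
  structure(list(
    magnitude_mean = mean(mags),
    magnitude_sd = stats::sd(mags),
    freq_bounds = c(0, 1000),
    octave_bounds = c(2, 12),
    patient_levels = subjects), class = "atom_scaler")
}

#' Apply the fitted scaler to raw atom features
#'
#' @param raw data frame from `raw_atom_features()`.
#' @param scaler an `atom_scaler`.
#' @param subject_id the sample's subject token (must be in the scaler's
#'   label map; an unseen subject is an explicit error, never a silent new
#'   code).
#' @return list with `features` (matrix with the 9 documented columns:
#'   `coefficient_magnitude`, `phase_sin`, `phase_cos`, `frequency`,
#'   `octave`, `influence_given`, `influence_received`,
#'   `low_octave_influence`, `high_octave_influence`) and `patient_code`
#'   (integer).
#' @export
scale_features <- function(raw, scaler, subject_id) {
  stopifnot(inherits(scaler, "atom_scaler"))
  code <- match(subject_id, scaler$patient_levels)
  if (is.na(code)) {
    stop("unseen patient ID at transform time: ", subject_id)
  }
  f <- cbind(
    coefficient_magnitude =
      (raw$coefficient_magnitude - scaler$magnitude_mean) /
        scaler$magnitude_sd,
    phase_sin = sin(raw$phase),
    phase_cos = cos(raw$phase),
    frequency = (raw$frequency - scaler$freq_bounds[1]) /
      diff(scaler$freq_bounds),
    octave = (raw$octave - scaler$octave_bounds[1]) /
      diff(scaler$octave_bounds),
    influence_given = raw$influence_given,
    influence_received = raw$influence_received,
    low_octave_influence = raw$low_octave_influence,
    high_octave_influence = raw$high_octave_influence)
  list(features = f, patient_code = as.integer(code))
}

# Invert the invertible scalings (magnitude / frequency / octave).
unscale_features <- function(features, scaler) {
  data.frame(
    coefficient_magnitude = features[, "coefficient_magnitude"] *
      scaler$magnitude_sd + scaler$magnitude_mean,
    frequency = features[, "frequency"] * diff(scaler$freq_bounds) +
      scaler$freq_bounds[1],
    octave = features[, "octave"] * diff(scaler$octave_bounds) +
      scaler$octave_bounds[1])
}

#' Serialize / restore scaler state as JSON
#' @param scaler an `atom_scaler`.
#' @param path file path.
#' @export
scaler_to_json <- function(scaler, path) {
  jsonlite::write_json(unclass(scaler), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname scaler_to_json
#' @export
scaler_from_json <- function(path) {
  s <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(magnitude_mean = s$magnitude_mean,
                 magnitude_sd = s$magnitude_sd,
                 freq_bounds = as.numeric(s$freq_bounds),
                 octave_bounds = as.numeric(s$octave_bounds),
                 patient_levels = as.character(s$patient_levels)),
            class = "atom_scaler")
}

#' Assemble classification samples from labelled decompositions
#'
#' One sample record per decomposed segment: the raw per-atom feature table,
#' the class label (pre = 0, post = 1), and provenance. Scaling is applied
#' afterwards with [apply_scaler()] so the scaler can be fitted on the
#' training split alone. Decompositions with zero atoms are skipped with a
#' warning.
#'
#' @param decompositions list of [decompose()] results whose `segment_ref`
#'   carries `subject_id` and `condition`.
#' @return list of sample records (`raw`, `label`, `subject_id`, `segment_kind`,
#'   `start_sample`, `decomposition_index`).
#' @export
assemble_samples <- function(decompositions) {
  out <- list()
  for (i in seq_along(decompositions)) {
    d <- decompositions[[i]]
    ref <- attr(d, "segment_ref")
    if (nrow(d) == 0) {
      warning("skipping decomposition ", i, " with zero atoms")
      next
    }
    stopifnot(ref$condition %in% c("pre", "post"))
    out[[length(out) + 1L]] <- list(
      raw = raw_atom_features(d),
      label = if (ref$condition == "pre") 0L else 1L,
      subject_id = ref$subject_id,
      segment_kind = ref$kind,
      start_sample = ref$start_sample,
      decomposition_index = i)
  }
  out
}

#' Apply a fitted scaler to assembled samples
#'
#' @param samples from [assemble_samples()].
#' @param scaler from [fit_scaler()].
#' @param include_patient_id append the encoded patient ID as a constant
#'   extra feature column (default `TRUE`, matching the feature table the
#'   set classifier consumes; set `FALSE` to ablate identity conditioning).
#' @return samples with `$features` (matrix `n_atoms x 9` or `x 10`) and
#'   `$patient_code` added.
#' @export
apply_scaler <- function(samples, scaler, include_patient_id = TRUE) {
  lapply(samples, function(s) {
    sc <- scale_features(s$raw, scaler, s$subject_id)
    f <- sc$features
    if (include_patient_id) {
      f <- cbind(f, patient_id = rep(sc$patient_code, nrow(f)))
    }
    s$features <- f
    s$patient_code <- sc$patient_code
    s
  })
}
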