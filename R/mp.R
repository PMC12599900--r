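# Gabor matching pursuit: dictionary description, decomposition, and
# reconstruction. The per-iteration search runs in compiled code
# (src/mp_core.cpp); this file owns the user-facing contracts.

.dict_cache <- new.env(parent = emptyenv())

#' Generate one unit-norm Gabor atom waveform
#'
#' `g(t) = K * exp(-pi*((t-u)/s)^2) * cos(2*pi*f*(t-u)/fs + phi)` with scale
#' `s = 2^octave` samples, envelope truncated at `|t-u| <= 4s` and to the
#' segment `[0, length)`, and `K` chosen so that `||g||_2 = 1`.
#'
#' @param octave dyadic scale exponent `j` (scale `2^j` samples).
#' @param frequency modulation frequency in Hz.
#' @param translation atom center `u`, a 0-based sample index in the segment.
#' @param phase phase in radians.
#' @param length segment length in samples.
#' @param fs sampling rate in Hz (default 4000).
#' @return numeric vector of `length` samples with unit L2 norm.
#' @export
atom_waveform <- function(octave, frequency, translation, phase, length,
                          fs = 4000) {
  s <- 2^octave
  T <- min(floor(4 * s), length - 1)
  t <- 0:(length - 1)
  tau <- t - translation
  g <- numeric(length)
  keep <- abs(tau) <= T
  g[keep] <- exp(-pi * (tau[keep] / s)^2) *
    cos(2 * pi * frequency * tau[keep] / fs + phase)
  nrm <- sqrt(sum(g^2))
  if (nrm < 1e-300) {
    stop("atom has zero norm after truncation (translation outside segment?)")
  }
  g / nrm
}

#' Describe the Gabor dictionary parameter grid for a segment length
#'
#' For each octave `j` the frequency grid is `k * fs / 2^j` for integer
#' `k >= 0` up to `freq_cap`; translations are all integer samples in the
#' segment (searched implicitly via FFT correlation, never enumerated) and the
#' phase is computed analytically per candidate during [decompose()].
#'
#' @param length segment length in samples.
#' @param octave_range integer `c(min, max)`; clipped to
#'   `[octave_range[1], floor(log2(length))]`.
#' @param freq_cap maximum dictionary frequency in Hz (default 1000).
#' @param fs sampling rate in Hz.
#' @return object of class `gabor_dictionary` with the octave set, per-octave
#'   frequency grids, and a handle to the precomputed FFT search tables.
#' @export
build_dictionary <- function(length, octave_range = c(2L, 12L),
                             freq_cap = 1000, fs = 4000) {
  stopifnot(length >= 4, octave_range[1] >= 1)
  j_max <- min(octave_range[2], floor(log2(length)))
  if (j_max < octave_range[1]) {
    stop("octave range empty after clipping to floor(log2(length))")
  }
  octaves <- seq.int(octave_range[1], j_max)
  freqs <- lapply(octaves, function(j) {
    k <- 0:floor(freq_cap * 2^j / fs + 1e-9)
    k * fs / 2^j
  })
  names(freqs) <- as.character(octaves)
  key <- paste(length, fs, freq_cap, paste(octaves, collapse = ","), sep = "|")
  ptr <- .dict_cache[[key]]
  if (is.null(ptr)) {
    ptr <- gabor_dict_build(as.integer(length), fs, as.integer(octaves),
                            freq_cap)
    .dict_cache[[key]] <- ptr
  }
  structure(
    list(length = as.integer(length), fs = fs, octaves = octaves,
         frequencies = freqs, freq_cap = freq_cap, ptr = ptr, key = key),
    class = "gabor_dictionary")
}

#' @exportS3Method base::print
print.gabor_dictionary <- function(x, ...) {
  cat(sprintf("Gabor dictionary: length %d @ %g Hz, octaves %d..%d, %d (octave, frequency) pairs\n",
              x$length, x$fs, min(x$octaves), max(x$octaves),
              sum(lengths(x$frequencies))))
  invisible(x)
}

#' Greedy matching-pursuit decomposition of a segment
#'
#' Per iteration, the correlation of the residual with the complex Gabor
#' kernel is computed over all translations via FFT for every (octave,
#' frequency) pair; the optimal phase per candidate derives analytically from
#' the complex projection; the globally best candidate is extracted and its
#' projection subtracted from the residual. Extraction stops at `n_atoms`
#' atoms or when the residual energy falls below `1e-12` of the original.
#' Argmax ties break deterministically toward lower octave, then lower
#' frequency, then earlier translation.
#'
#' @param segment a [pcg_segment] or numeric vector.
#' @param n_atoms maximum number of atoms (default 100, one sample's worth).
#' @param dictionary optional [build_dictionary()] result (built and cached
#'   automatically when `NULL`).
#' @param fs sampling rate in Hz, used when `segment` is a bare vector.
#' @param octave_range,freq_cap dictionary parameters, see
#'   [build_dictionary()].
#' @return object of class `gabor_decomposition`: a data frame of atoms in
#'   extraction order (`iteration`, `octave`, `frequency_hz`, `translation`,
#'   `phase`, `coefficient_magnitude`) with attributes `residual_energy`,
#'   `residual_energies`, `initial_energy`, `length`, `fs`, `segment_ref`.
#' @export
decompose <- function(segment, n_atoms = 100L, dictionary = NULL, fs = 4000,
                      octave_range = c(2L, 12L), freq_cap = 1000) {
  if (inherits(segment, "pcg_segment")) {
    x <- segment$samples
    fs <- segment$sample_rate
    segment_ref <- list(subject_id = segment$subject_id,
                        condition = segment$condition,
                        kind = segment$kind,
                        start_sample = segment$start_sample)
  } else {
    x <- as.numeric(segment)
    segment_ref <- list(subject_id = NA_character_, condition = NA_character_,
                        kind = "raw", start_sample = 0L)
  }
  stopifnot(n_atoms >= 1)
  stop_if_not_finite(x, "segment samples")
  if (all(x == 0)) {
    atoms <- data.frame(iteration = integer(0), octave = integer(0),
                        frequency_hz = numeric(0), translation = integer(0),
                        phase = numeric(0), coefficient_magnitude = numeric(0))
    return(new_decomposition(atoms, residual_energy = 0,
                             residual_energies = numeric(0),
                             initial_energy = 0, length = length(x), fs = fs,
                             segment_ref = segment_ref))
  }
  if (is.null(dictionary)) {
    dictionary <- build_dictionary(length(x), octave_range, freq_cap, fs)
  }
  stopifnot(dictionary$length == length(x), dictionary$fs == fs)
  res <- mp_decompose_fft(x, dictionary$ptr, as.integer(n_atoms), 1e-12)
  atoms <- as.data.frame(res$atoms)
  atoms$iteration <- as.integer(atoms$iteration)
  atoms$octave <- as.integer(atoms$octave)
  atoms$translation <- as.integer(atoms$translation)
  new_decomposition(
    atoms,
    residual_energy = if (length(res$residual_energies))
      res$residual_energies[length(res$residual_energies)] else res$initial_energy,
    residual_energies = as.numeric(res$residual_energies),
    initial_energy = res$initial_energy,
    length = length(x), fs = fs, segment_ref = segment_ref)
}

new_decomposition <- function(atoms, residual_energy, residual_energies,
                              initial_energy, length, fs, segment_ref) {
  structure(atoms,
            residual_energy = residual_energy,
            residual_energies = residual_energies,
            initial_energy = initial_energy,
            length = as.integer(length),
            fs = fs,
            segment_ref = segment_ref,
            class = c("gabor_decomposition", "data.frame"))
}

#' @exportS3Method base::print
print.gabor_decomposition <- function(x, ...) {
  ref <- attr(x, "segment_ref")
  cat(sprintf("Gabor decomposition: %d atoms over %d samples (%s, %s, %s)\n",
              nrow(x), attr(x, "length"), ref$subject_id %||% NA,
              ref$condition %||% NA, ref$kind %||% NA))
  cat(sprintf("  initial energy %.6g, residual energy %.6g\n",
              attr(x, "initial_energy"), attr(x, "residual_energy")))
  invisible(x)
}

#' Reconstruct a signal from a subset of atoms
#'
#' Linear superposition `sum_i c_i * g_i` over the selected atoms;
#' `reconstruct(A union B) = reconstruct(A) + reconstruct(B)` for disjoint
#' subsets.
#'
#' @param decomposition a [decompose()] result.
#' @param atom_subset integer indices (1-based rows of the atom table) or
#'   `"all"`.
#' @param length output length in samples (defaults to the decomposed
#'   segment's length).
#' @return numeric vector.
#' @export
reconstruct <- function(decomposition, atom_subset = "all", length = NULL) {
  stopifnot(inherits(decomposition, "gabor_decomposition"))
  n <- length %||% attr(decomposition, "length")
  fs <- attr(decomposition, "fs")
  if (identical(atom_subset, "all")) atom_subset <- seq_len(nrow(decomposition))
  stopifnot(all(atom_subset >= 1), all(atom_subset <= nrow(decomposition)))
  out <- numeric(n)
  for (i in atom_subset) {
    a <- decomposition[i, ]
    out <- out + a$coefficient_magnitude *
      atom_waveform(a$octave, a$frequency_hz, a$translation, a$phase, n, fs)
  }
  out
}
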