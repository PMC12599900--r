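# Interpretation: per-atom latents from the trained set classifier, 2-D
# embedding, density clustering, selective per-cluster reconstruction, and
# pre -> post band-power change analysis with monotonic grouping.

#' Extract per-atom latent representations from a trained model
#'
#' One latent vector per atom over the supplied samples, in eval mode. The
#' latent is the atom-encoder output, which precedes pooling, so an atom's
#' latent depends only on its own feature row.
#'
#' @param model a trained `deepset_model`.
#' @param samples scaled sample list.
#' @return list with `latents` (matrix `total_atoms x latent_dim`) and
#'   `provenance` (data frame: `sample_index`, `atom_index` within sample,
#'   `subject_id`, `condition` label, `segment_kind`, `start_sample`,
#'   `decomposition_index`).
#' @export
extract_latents <- function(model, samples) {
  stopifnot(inherits(model, "deepset_model"))
  if (ncol(samples[[1]]$features) != model$config$input_dim) {
    stop("feature dimensionality does not match the model config")
  }
  st <- stack_samples(samples)
  fw <- deepset_forward(model, st$X, st$sid, st$n, train = FALSE)
  prov <- do.call(rbind, lapply(seq_along(samples), function(i) {
    s <- samples[[i]]
    data.frame(sample_index = i,
               atom_index = seq_len(nrow(s$features)),
               subject_id = s$subject_id,
               label = s$label,
               segment_kind = s$segment_kind,
               start_sample = s$start_sample,
               decomposition_index = s$decomposition_index,
               stringsAsFactors = FALSE)
  }))
  list(latents = fw$latent, provenance = prov)
}

#' Embed atom latents in two dimensions (UMAP)
#'
#' Nonlinear neighbor-graph embedding to 2 components with a fixed seed;
#' `scope = "per_subject"` embeds each subject's atoms independently
#' (coordinates are then comparable only within a subject).
#'
#' @param latents latent matrix (or [extract_latents()] output).
#' @param scope `"cohort"` or `"per_subject"`.
#' @param seed embedding seed.
#' @param n_neighbors neighborhood size (default 15; reduced with a warning
#'   when fewer points are available).
#' @param subject_ids required for `scope = "per_subject"`.
#' @return matrix `n_atoms x 2`.
#' @export
embed_latents <- function(latents, scope = c("cohort", "per_subject"),
                          seed = 1L, n_neighbors = 15L, subject_ids = NULL) {
  scope <- match.arg(scope)
  if (is.list(latents) && !is.null(latents$latents)) {
    if (is.null(subject_ids)) subject_ids <- latents$provenance$subject_id
    latents <- latents$latents
  }
  stopifnot(nrow(latents) >= 10)
  embed_one <- function(x) {
    nb <- n_neighbors
    if (nrow(x) <= nb) {
      nb <- max(2L, nrow(x) - 1L)
      warning("fewer points than n_neighbors; reduced to ", nb)
    }
    with_seed(seed, {
      uwot::umap(x, n_components = 2, n_neighbors = nb, min_dist = 0.1,
                 n_threads = 1, n_sgd_threads = 0, batch = FALSE,
                 verbose = FALSE)
    })
  }
  if (scope == "cohort") {
    out <- embed_one(latents)
  } else {
    stopifnot(!is.null(subject_ids), length(subject_ids) == nrow(latents))
    out <- matrix(NA_real_, nrow(latents), 2)
    for (s in unique(subject_ids)) {
      rows <- which(subject_ids == s)
      out[rows, ] <- embed_one(latents[rows, , drop = FALSE])
    }
  }
  colnames(out) <- c("umap1", "umap2")
  out
}

#' Density-based clustering (DBSCAN) of a 2-D embedding
#'
#' Exact DBSCAN with Euclidean distance, radius `eps` and `min_points`
#' minimum neighborhood size (the point itself included) for dense-region
#' formation; neighbor queries use a grid of `eps`-sized cells. Points in no
#' dense region are noise (`-1`); cluster labels are renumbered `0..K-1` by
#' descending cluster size.
#'
#' @param embedding `n x 2` coordinate matrix.
#' @param eps neighborhood radius (default 0.5).
#' @param min_points minimum points for a dense region (default 5).
#' @return integer vector of cluster ids (`-1` = noise).
#' @export
cluster_atoms <- function(embedding, eps = 0.5, min_points = 5L) {
  stopifnot(ncol(embedding) == 2)
  n <- nrow(embedding)
  x <- embedding[, 1]; y <- embedding[, 2]
  cx <- floor(x / eps); cy <- floor(y / eps)
  key <- paste(cx, cy)
  cell_of <- split(seq_len(n), key)
  neighbors <- function(i) {
    cand <- integer(0)
    for (dx in -1:1) for (dy in -1:1) {
      k <- paste(cx[i] + dx, cy[i] + dy)
      cand <- c(cand, cell_of[[k]])
    }
    cand[(x[cand] - x[i])^2 + (y[cand] - y[i])^2 <= eps^2]
  }
  nb <- lapply(seq_len(n), neighbors)
  core <- lengths(nb) >= min_points
  labels <- rep(-2L, n)  # -2 = unvisited, -1 = noise
  cl <- -1L
  for (i in seq_len(n)) {
    if (labels[i] != -2L || !core[i]) next
    cl <- cl + 1L
    labels[i] <- cl
    queue <- nb[[i]]
    while (length(queue)) {
      q <- queue[[1]]
      queue <- queue[-1]
      if (labels[q] == -1L) labels[q] <- cl        # noise -> border
      if (labels[q] != -2L) next
      labels[q] <- cl
      if (core[q]) queue <- c(queue, nb[[q]])
    }
  }
  labels[labels == -2L] <- -1L
  # renumber by descending size (ties: lower original label first)
  if (cl >= 0L) {
    sizes <- table(factor(labels[labels >= 0L], levels = 0:cl))
    remap <- order(-as.integer(sizes), as.integer(names(sizes)))
    new <- integer(cl + 1L)
    new[remap] <- 0:cl
    labels[labels >= 0L] <- new[labels[labels >= 0L] + 1L]
  }
  labels
}

#' Per-cluster selective reconstruction on the recording timeline
#'
#' Atoms of one cluster are summed into their segments' positions within the
#' recording (overlap-add; samples covered by two 50%-overlapping windows
#' get weight 0.5, i.e. the per-sample weight is 1/coverage computed over
#' all decompositions of that condition). The raw reconstruction is then
#' smoothed with a Gaussian kernel (`sigma` = 5 samples) and band-pass
#' filtered (5th-order Butterworth, 65-400 Hz, applied forward-backward so
#' the result is zero-phase).
#'
#' @param decompositions list of [decompose()] results with segment
#'   provenance (all of one condition for one recording timeline).
#' @param cluster_ids integer cluster label per atom, ordered as the atoms
#'   of `decompositions` concatenated in list order.
#' @param recording_length timeline length in samples.
#' @param fs sampling rate in Hz.
#' @param clusters which cluster ids to reconstruct (default: all present,
#'   including noise `-1`).
#' @param sigma Gaussian smoothing width in samples (default 5).
#' @param band band-pass edges in Hz (default `c(65, 400)`).
#' @param filter_order Butterworth prototype order (default 5).
#' @return list per cluster id (named) with `raw` and `filtered` signals of
#'   `recording_length` samples; empty clusters give zero signals with a
#'   warning. The unfiltered reconstructions over all clusters sum to the
#'   full-atom reconstruction exactly.
#' @export
cluster_reconstruction <- function(decompositions, cluster_ids,
                                   recording_length, fs = 4000,
                                   clusters = NULL, sigma = 5,
                                   band = c(65, 400), filter_order = 5L) {
  n_atoms <- vapply(decompositions, nrow, integer(1))
  stopifnot(length(cluster_ids) == sum(n_atoms))
  if (is.null(clusters)) clusters <- sort(unique(cluster_ids))
  # coverage: number of windows covering each timeline sample
  coverage <- numeric(recording_length)
  for (d in decompositions) {
    s0 <- attr(d, "segment_ref")$start_sample
    len <- attr(d, "length")
    coverage[(s0 + 1):(s0 + len)] <- coverage[(s0 + 1):(s0 + len)] + 1
  }
  weight <- ifelse(coverage > 0, 1 / pmax(coverage, 1), 0)
  sos <- butter_bandpass(filter_order, band[1], band[2], fs)
  offsets <- c(0L, cumsum(n_atoms))
  out <- list()
  for (cl in clusters) {
    raw <- numeric(recording_length)
    any_atom <- FALSE
    for (i in seq_along(decompositions)) {
      d <- decompositions[[i]]
      rows <- which(cluster_ids[(offsets[i] + 1):offsets[i + 1]] == cl)
      if (!length(rows)) next
      any_atom <- TRUE
      s0 <- attr(d, "segment_ref")$start_sample
      len <- attr(d, "length")
      seg <- reconstruct(d, rows)
      raw[(s0 + 1):(s0 + len)] <- raw[(s0 + 1):(s0 + len)] + seg
    }
    if (!any_atom) warning("cluster ", cl, " has no atoms; zero signal")
    raw <- raw * weight
    filtered <- sos_filtfilt(sos, gauss_smooth(raw, sigma))
    out[[as.character(cl)]] <- list(cluster_id = cl, raw = raw,
                                    filtered = filtered)
  }
  out
}

#' Mean cardiac-cycle power with standard error
#'
#' Cycles run diastole start to diastole start (diastole start = S2 onset +
#' 100 ms); per cycle the mean squared amplitude is computed, and the mean
#' and standard error (`sd / sqrt(n_cycles)`) over cycles are reported.
#'
#' @param signal reconstruction time series.
#' @param diastole_starts 0-based cycle boundary indices (at least 2).
#' @return list with `mean`, `se`, `n_cycles`, `per_cycle`.
#' @export
cycle_power <- function(signal, diastole_starts) {
  stopifnot(length(diastole_starts) >= 2)
  ds <- sort(as.integer(diastole_starts))
  per <- vapply(seq_len(length(ds) - 1L), function(i) {
    seg <- signal[(ds[i] + 1L):min(ds[i + 1L], length(signal))]
    mean(seg^2)
  }, numeric(1))
  n <- length(per)
  list(mean = mean(per),
       se = if (n > 1) stats::sd(per) / sqrt(n) else 0,
       n_cycles = n, per_cycle = per)
}

#' Band-power change between two conditions
#'
#' STFT band power ([band_powers()]: Hann window 256, hop 128) in eight
#' 50-Hz bands from 0 to 400 Hz for each signal; delta = post - pre.
#'
#' @param pre,post reconstruction time series (same sampling rate).
#' @param fs sampling rate in Hz.
#' @param band_edges band edges (default `seq(0, 400, 50)`).
#' @param win,hop STFT parameters.
#' @return data frame with `band`, `pre`, `post`, `delta`.
#' @export
band_power_change <- function(pre, post, fs = 4000,
                              band_edges = seq(0, 400, by = 50),
                              win = 256L, hop = 128L) {
  bp_pre <- band_powers(pre, fs, band_edges, win, hop)
  bp_post <- band_powers(post, fs, band_edges, win, hop)
  data.frame(band = names(bp_pre), pre = as.numeric(bp_pre),
             post = as.numeric(bp_post),
             delta = as.numeric(bp_post - bp_pre))
}

#' Monotonic grouping of a cluster's low-band power deltas
#'
#' Uses the deltas of the 0-50, 50-100 and 100-150 Hz bands: `"increase"` if
#' all three exceed `-tolerance` with at least one above `+tolerance`;
#' `"decrease"` if all three are below `tolerance` with at least one below
#' `-tolerance`; otherwise (including all-within-tolerance) `"mixed"`.
#'
#' @param deltas numeric vector of band deltas for the three bands below
#'   150 Hz (extra bands are ignored).
#' @param tolerance sign tolerance (default `1e-6`).
#' @return `"increase"`, `"decrease"` or `"mixed"`.
#' @export
group_clusters <- function(deltas, tolerance = 1e-6) {
  d <- deltas[1:3]
  if (all(d > -tolerance) && any(d > tolerance)) return("increase")
  if (all(d < tolerance) && any(d < -tolerance)) return("decrease")
  "mixed"
}

#' Full per-cluster report for one subject
#'
#' Combines per-cluster reconstructions of the pre and post recordings,
#' cycle power (mean +/- SE per condition), the eight 50-Hz band powers and
#' deltas, and the monotonic group label.
#'
#' @param recon_pre,recon_post outputs of [cluster_reconstruction()] for the
#'   two conditions (same cluster set).
#' @param diastole_pre,diastole_post 0-based diastole start indices.
#' @param fs sampling rate in Hz.
#' @param tolerance grouping tolerance.
#' @return data frame, one row per cluster x band, with cycle-power columns
#'   and the cluster's group label repeated across its rows.
#' @export
cluster_report <- function(recon_pre, recon_post, diastole_pre,
                           diastole_post, fs = 4000, tolerance = 1e-6) {
  ids <- intersect(names(recon_pre), names(recon_post))
  rows <- list()
  for (id in ids) {
    sig_pre <- recon_pre[[id]]$filtered
    sig_post <- recon_post[[id]]$filtered
    bpc <- band_power_change(sig_pre, sig_post, fs)
    cp_pre <- cycle_power(sig_pre, diastole_pre)
    cp_post <- cycle_power(sig_post, diastole_post)
    grp <- group_clusters(bpc$delta, tolerance)
    rows[[id]] <- cbind(
      data.frame(cluster_id = recon_pre[[id]]$cluster_id,
                 group = grp,
                 cycle_power_pre = cp_pre$mean, cycle_power_pre_se = cp_pre$se,
                 cycle_power_post = cp_post$mean,
                 cycle_power_post_se = cp_post$se,
                 stringsAsFactors = FALSE),
      bpc)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
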