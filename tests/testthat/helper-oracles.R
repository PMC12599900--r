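# Independent reference implementations ("oracles") used to validate the
# package's fast paths. These deliberately share no code with the package
# internals beyond atom_waveform()'s public contract.

# --- exhaustive matching pursuit ------------------------------------------
# Enumerates every (octave, frequency, translation) candidate, computes the
# exact 2-D phase projection by direct summation, and extracts greedily with
# the same deterministic tie-break (lower octave, lower frequency, earlier
# translation). Basis matrices are precomputed per dictionary.

naive_mp_dictionary <- function(N, fs = 4000, octaves = 2:floor(log2(N)),
                                freq_cap = 1000) {
  pairs <- list()
  t <- 0:(N - 1)
  for (j in octaves) {
    s <- 2^j
    T <- min(4 * s, N - 1)
    for (f in (0:floor(freq_cap * s / fs + 1e-9)) * fs / s) {
      th <- 2 * pi * f / fs
      Wc <- matrix(0, N, N)  # column u: w(t-u) cos(th (t-u))
      Ws <- matrix(0, N, N)
      for (u in 0:(N - 1)) {
        tau <- t - u
        keep <- abs(tau) <= T
        w <- ifelse(keep, exp(-pi * (tau / s)^2), 0)
        Wc[, u + 1] <- w * cos(th * tau)
        Ws[, u + 1] <- w * sin(th * tau)
      }
      pairs[[length(pairs) + 1]] <- list(
        j = j, f = f, Wc = Wc, Ws = Ws,
        P = colSums(Wc^2), Q = colSums(Ws^2), S = colSums(Wc * Ws))
    }
  }
  pairs
}

naive_mp <- function(x, n_atoms, dict_pairs, fs = 4000) {
  N <- length(x)
  res <- x
  out <- NULL
  for (it in seq_len(n_atoms)) {
    best <- list(E = -1, j = Inf, f = Inf, u = Inf)
    for (pr in dict_pairs) {
      a <- as.numeric(crossprod(pr$Wc, res))
      b <- as.numeric(crossprod(pr$Ws, res))
      if (pr$f == 0) {
        E <- ifelse(pr$P > 0, a^2 / pmax(pr$P, 1e-300), 0)
      } else {
        det <- pr$P * pr$Q - pr$S^2
        ok <- det > 1e-12 * (abs(pr$P * pr$Q) + pr$S^2)
        E <- ifelse(ok,
                    (pr$Q * a^2 - 2 * pr$S * a * b + pr$P * b^2) /
                      ifelse(ok, det, 1),
                    pmax(a^2 / pmax(pr$P, 1e-300),
                         ifelse(pr$Q > 0, b^2 / pmax(pr$Q, 1e-300), 0)))
      }
      u_best <- which.max(E) - 1L
      Eb <- E[u_best + 1L]
      better <- Eb > best$E ||
        (Eb == best$E && (pr$j < best$j || (pr$j == best$j &&
         (pr$f < best$f || (pr$f == best$f && u_best < best$u)))))
      if (better) {
        best <- list(E = Eb, j = pr$j, f = pr$f, u = u_best,
                     a = a[u_best + 1L], b = b[u_best + 1L],
                     P = pr$P[u_best + 1L], Q = pr$Q[u_best + 1L],
                     S = pr$S[u_best + 1L])
      }
    }
    if (best$f == 0) {
      phi <- if (best$a >= 0) 0 else pi
    } else {
      det <- best$P * best$Q - best$S^2
      if (det <= 1e-12 * (abs(best$P * best$Q) + best$S^2)) {
        if (best$a^2 / best$P >= ifelse(best$Q > 0, best$b^2 / best$Q, 0)) {
          phi <- if (best$a >= 0) 0 else pi
        } else {
          phi <- if (best$b >= 0) -pi / 2 else pi / 2
        }
      } else {
        x1 <- (best$Q * best$a - best$S * best$b) / det
        x2 <- (-best$S * best$a + best$P * best$b) / det
        phi <- atan2(-x2, x1)
      }
    }
    g <- atom_waveform(best$j, best$f, best$u, phi, N, fs)
    cc <- sum(res * g)
    if (cc < 0) {
      phi <- phi + pi
      if (phi > pi) phi <- phi - 2 * pi
      cc <- -cc
      g <- -g
    }
    res <- res - cc * g
    out <- rbind(out, data.frame(octave = best$j, frequency_hz = best$f,
                                 translation = best$u, phase = phi,
                                 coefficient_magnitude = cc))
  }
  list(atoms = out, residual = res)
}

# --- brute-force influence counts -----------------------------------------
naive_influence <- function(atoms) {
  n <- nrow(atoms)
  out <- data.frame(influence_given = integer(n),
                    influence_received = integer(n),
                    low_octave_influence = integer(n),
                    high_octave_influence = integer(n))
  for (a in seq_len(n)) {
    for (b in seq_len(n)) {
      if (a == b) next
      ov <- abs(atoms$translation[a] - atoms$translation[b]) <
        (2^atoms$octave[a] + 2^atoms$octave[b]) / 2
      if (!ov) next
      if (atoms$iteration[b] > atoms$iteration[a]) {
        out$influence_given[a] <- out$influence_given[a] + 1L
      } else {
        out$influence_received[a] <- out$influence_received[a] + 1L
      }
      if (atoms$octave[b] < atoms$octave[a]) {
        out$low_octave_influence[a] <- out$low_octave_influence[a] + 1L
      }
      if (atoms$octave[b] > atoms$octave[a]) {
        out$high_octave_influence[a] <- out$high_octave_influence[a] + 1L
      }
    }
  }
  out
}

# Random atom tables standing in for decompositions (influence features only
# need octave/translation/iteration).
random_atom_table <- function(n, N = 512, octaves = 2:9) {
  data.frame(iteration = 0:(n - 1),
             octave = sample(octaves, n, replace = TRUE),
             translation = sample(0:(N - 1), n, replace = TRUE))
}

# --- brute-force DBSCAN (density reachability via BFS) --------------------
naive_dbscan <- function(X, eps, min_pts) {
  n <- nrow(X)
  D <- as.matrix(stats::dist(X))
  nb <- lapply(seq_len(n), function(i) which(D[i, ] <= eps))
  core <- lengths(nb) >= min_pts
  labels <- rep(-2L, n)
  cl <- -1L
  for (i in seq_len(n)) {
    if (labels[i] != -2L || !core[i]) next
    cl <- cl + 1L
    labels[i] <- cl
    queue <- nb[[i]]
    while (length(queue)) {
      q <- queue[[1]]
      queue <- queue[-1]
      if (labels[q] == -1L) labels[q] <- cl
      if (labels[q] != -2L) next
      labels[q] <- cl
      if (core[q]) queue <- c(queue, nb[[q]])
    }
  }
  labels[labels == -2L] <- -1L
  labels
}

# Cluster labellings agree up to renaming.
same_partition <- function(a, b) {
  if (length(a) != length(b)) return(FALSE)
  if (!all((a == -1) == (b == -1))) return(FALSE)
  keep <- a != -1
  length(unique(paste(a[keep], b[keep]))) ==
    length(unique(a[keep])) &&
    length(unique(a[keep])) == length(unique(b[keep]))
}
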