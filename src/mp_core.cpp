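// Matching-pursuit core: Gabor dictionary with an FFT-accelerated
// inner-product search over all integer translations, plus a small IIR (SOS)
// filter kernel.
//
// Gabor atom: g(t) = K * exp(-pi*((t-u)/s)^2) * cos(2*pi*f*(t-u)/fs + phi),
// s = 2^j samples, envelope truncated at |t-u| <= 4s and to the segment,
// K chosen so ||g||_2 = 1.
//
// Search: the dictionary's frequency grid is f = k*fs/2^j, so the complex
// correlation at every frequency of one octave,
//   Z_k(u) = sum_tau r(u+tau) w(tau) exp(2*pi*i*k*tau/s),
// is exactly the length-s DFT of the residual folded modulo s under the
// envelope: Z_k(u) = conj(DFT_s(F_u)[k]) with
//   F_u(p) = sum_q r(u + q*s + p) w(q*s + p).
// The DFTs are batched over translations u (radix-2, butterflies contiguous
// across the batch), replacing per-frequency full-length transforms. The
// optimal phase at each candidate comes from projecting onto the 2-D span of
// (w*cos, w*sin) with the exact Gram matrix G = [[P,S],[S,Q]] (precomputed
// per pair including segment-edge truncation), giving the best squared
// projection E(u) = v' G^-1 v with v = (Re Z, Im Z).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

struct GaborPair {
  int oct_idx;
  int j;
  int k;              // frequency index: f = k*fs/2^j
  double freq;        // Hz
  arma::vec P, Q, S;  // Gram terms per translation u in [0, N)
};

struct FftTables {
  int n = 0;
  std::vector<int> bitrev;
  std::vector<double> twr, twi;  // e^{-2*pi*i*k/n}, k < n/2
};

struct GaborOctave {
  int j;
  int s;                 // scale 2^j
  int T;                 // envelope truncation half-width (samples)
  int pair_lo, pair_hi;  // index range into pairs [lo, hi)
  arma::vec w;           // envelope on tau = -T..T
  FftTables full;        // length-s tables (dictionary build)
  FftTables half;        // length-s/2 tables (real-input packed search)
};

struct GaborDict {
  int N;
  double fs;
  std::vector<GaborOctave> octs;
  std::vector<GaborPair> pairs;
};

// Batch size (translations per fold/FFT block), capped so workspace stays
// around 16 MB per real/imag buffer.
static int chunk_cols(int s, int N) {
  int c = std::max(1, (1 << 21) / s);
  return std::min(c, N);
}

static void init_fft_tables(FftTables& ft, int n) {
  ft.n = n;
  ft.bitrev.assign(n, 0);
  int lg = 0;
  while ((1 << lg) < n) ++lg;
  for (int i = 0; i < n; ++i) {
    int r = 0;
    for (int b = 0; b < lg; ++b) if (i & (1 << b)) r |= 1 << (lg - 1 - b);
    ft.bitrev[i] = r;
  }
  ft.twr.assign(std::max(n / 2, 1), 0.0);
  ft.twi.assign(std::max(n / 2, 1), 0.0);
  for (int k = 0; k < n / 2; ++k) {
    ft.twr[k] = std::cos(-2.0 * M_PI * k / n);
    ft.twi[k] = std::sin(-2.0 * M_PI * k / n);
  }
}

// Forward DFT over the p-axis for C stacked rows: layout x[u + p*C],
// u = 0..C-1 contiguous per column p. In-place, imaginary part must be
// initialized (zero for real input).
static void batch_fft(double* re, double* im, int C, const FftTables& ft) {
  int s = ft.n;
  // bit-reversal permutation of columns
  for (int p = 0; p < s; ++p) {
    int q = ft.bitrev[p];
    if (q > p) {
      std::swap_ranges(re + (size_t)p * C, re + (size_t)(p + 1) * C,
                       re + (size_t)q * C);
      std::swap_ranges(im + (size_t)p * C, im + (size_t)(p + 1) * C,
                       im + (size_t)q * C);
    }
  }
  for (int len = 2; len <= s; len <<= 1) {
    int half = len >> 1;
    int step = s / len;
    for (int start = 0; start < s; start += len) {
      for (int m = 0; m < half; ++m) {
        double wr = ft.twr[(size_t)m * step];
        double wi = ft.twi[(size_t)m * step];
        double* r1 = re + (size_t)(start + m) * C;
        double* i1 = im + (size_t)(start + m) * C;
        double* r2 = re + (size_t)(start + m + half) * C;
        double* i2 = im + (size_t)(start + m + half) * C;
        for (int u = 0; u < C; ++u) {
          double tr = wr * r2[u] - wi * i2[u];
          double ti = wr * i2[u] + wi * r2[u];
          r2[u] = r1[u] - tr;
          i2[u] = i1[u] - ti;
          r1[u] += tr;
          i1[u] += ti;
        }
      }
    }
  }
}

// Fold x (zero outside [0, N)) against weights v(tau), tau = -T..T, modulo s,
// for translations u in [u0, u1): out[u - u0 + p*C] += x(u+tau) * v(tau).
static void fold_mod_s(const double* x, int N, const arma::vec& v, int T,
                       int s, int u0, int u1, int C, double* out) {
  std::fill(out, out + (size_t)C * s, 0.0);
  for (int tau = -T; tau <= T; ++tau) {
    double vt = v(tau + T);
    if (vt == 0.0) continue;
    int p = ((tau % s) + s) % s;
    int lo = std::max(u0, -tau);
    int hi = std::min(u1 - 1, N - 1 - tau);
    if (lo > hi) continue;
    double* col = out + (size_t)p * C - u0;
    for (int u = lo; u <= hi; ++u) col[u] += vt * x[u + tau];
  }
}

// Packed real-input variant: even residues p go to re[u + (p/2)*C], odd to
// im[u + (p/2)*C], forming z(p') = F(2p') + i*F(2p'+1) for a half-length FFT.
static void fold_mod_s_packed(const double* x, int N, const arma::vec& v,
                              int T, int s, int u0, int u1, int C,
                              double* re, double* im) {
  int s2 = s / 2;
  std::fill(re, re + (size_t)C * s2, 0.0);
  std::fill(im, im + (size_t)C * s2, 0.0);
  for (int tau = -T; tau <= T; ++tau) {
    double vt = v(tau + T);
    if (vt == 0.0) continue;
    int p = ((tau % s) + s) % s;
    int lo = std::max(u0, -tau);
    int hi = std::min(u1 - 1, N - 1 - tau);
    if (lo > hi) continue;
    double* col = ((p & 1) ? im : re) + (size_t)(p >> 1) * C - u0;
    for (int u = lo; u <= hi; ++u) col[u] += vt * x[u + tau];
  }
}

struct Workspace {
  std::vector<double> re, im;
  void ensure(size_t n) {
    if (re.size() < n) { re.resize(n); im.resize(n); }
  }
};

// [[Rcpp::export]]
SEXP gabor_dict_build(int N, double fs, IntegerVector octaves, double freq_cap) {
  GaborDict* dict = new GaborDict();
  dict->N = N;
  dict->fs = fs;
  std::vector<double> ones((size_t)N, 1.0);
  Workspace ws;
  for (int oi = 0; oi < octaves.size(); ++oi) {
    int j = octaves[oi];
    int s = 1 << j;
    double sd = (double)s;
    int T = std::min(4 * s, N - 1);
    GaborOctave oc;
    oc.j = j; oc.s = s; oc.T = T;
    oc.w = arma::vec(2 * T + 1);
    for (int tau = -T; tau <= T; ++tau)
      oc.w(tau + T) = std::exp(-M_PI * (tau / sd) * (tau / sd));
    init_fft_tables(oc.full, s);
    init_fft_tables(oc.half, s / 2);
    arma::vec w2 = arma::square(oc.w);

    int K = (int)std::floor(freq_cap * s / fs + 1e-9);
    oc.pair_lo = (int)dict->pairs.size();
    for (int k = 0; k <= K; ++k) {
      GaborPair pr;
      pr.oct_idx = (int)dict->octs.size();
      pr.j = j; pr.k = k;
      pr.freq = k * fs / sd;
      pr.P.set_size(N); pr.Q.set_size(N); pr.S.set_size(N);
      dict->pairs.push_back(pr);
    }
    oc.pair_hi = (int)dict->pairs.size();

    // Gram terms via the same fold + batched-DFT path:
    // V_m(u) = sum_tau 1_[0,N)(u+tau) w(tau)^2 e^{2*pi*i*m*tau/s}
    //        = conj(DFT_s(G_u)[m]),  m = 2k mod s; m = 0 gives ||w_u||^2.
    int C = chunk_cols(s, N);
    ws.ensure((size_t)C * s);
    for (int u0 = 0; u0 < N; u0 += C) {
      int u1 = std::min(u0 + C, N);
      fold_mod_s(ones.data(), N, w2, T, s, u0, u1, C, ws.re.data());
      std::fill(ws.im.begin(), ws.im.begin() + (size_t)C * s, 0.0);
      batch_fft(ws.re.data(), ws.im.data(), C, oc.full);
      for (int k = 0; k <= K; ++k) {
        GaborPair& pr = dict->pairs[oc.pair_lo + k];
        int m = (2 * k) % s;
        const double* xr0 = ws.re.data();                    // bin 0
        const double* xrm = ws.re.data() + (size_t)m * C;
        const double* xim = ws.im.data() + (size_t)m * C;
        for (int u = u0; u < u1; ++u) {
          double w2u = xr0[u - u0];
          if (k == 0) {
            pr.P(u) = w2u; pr.Q(u) = 0.0; pr.S(u) = 0.0;
          } else {
            double vr = xrm[u - u0];        // Re V
            double vi = -xim[u - u0];       // Im V = -Im DFT
            pr.P(u) = 0.5 * (w2u + vr);
            pr.Q(u) = 0.5 * (w2u - vr);
            pr.S(u) = 0.5 * vi;
          }
        }
      }
    }
    dict->octs.push_back(oc);
  }
  XPtr<GaborDict> ptr(dict, true);
  return ptr;
}

// [[Rcpp::export]]
List gabor_dict_info(SEXP dict_ptr) {
  XPtr<GaborDict> dict(dict_ptr);
  int np = dict->pairs.size();
  IntegerVector j(np);
  NumericVector f(np);
  for (int i = 0; i < np; ++i) {
    j[i] = dict->pairs[i].j;
    f[i] = dict->pairs[i].freq;
  }
  return List::create(_["length"] = dict->N, _["fs"] = dict->fs,
                      _["octave"] = j, _["frequency_hz"] = f);
}

// Unit-norm atom waveform over t in [0, N).
static arma::vec atom_wave(const GaborDict& dict, int oct_idx, double freq,
                           int u, double phi) {
  const GaborOctave& oc = dict.octs[oct_idx];
  int N = dict.N;
  double theta = 2.0 * M_PI * freq / dict.fs;
  arma::vec g(N, arma::fill::zeros);
  int lo = std::max(0, u - oc.T), hi = std::min(N - 1, u + oc.T);
  for (int t = lo; t <= hi; ++t) {
    int tau = t - u;
    g(t) = oc.w(tau + oc.T) * std::cos(theta * tau + phi);
  }
  double nrm = arma::norm(g, 2);
  if (nrm > 0) g /= nrm;
  return g;
}

static double wrap_phase(double phi) {
  while (phi > M_PI) phi -= 2.0 * M_PI;
  while (phi < -M_PI) phi += 2.0 * M_PI;
  return phi;
}

// [[Rcpp::export]]
List mp_decompose_fft(NumericVector x, SEXP dict_ptr, int n_atoms,
                      double tol_ratio) {
  XPtr<GaborDict> dict(dict_ptr);
  int N = dict->N;
  if (x.size() != N) stop("segment length does not match dictionary");
  arma::vec residual(x.begin(), N);
  double e0 = arma::dot(residual, residual);

  std::vector<double> rec_j, rec_f, rec_u, rec_phi, rec_c, rec_res;
  const double tiny = 1e-300;
  Workspace ws;

  for (int it = 0; it < n_atoms; ++it) {
    double res_e = arma::dot(residual, residual);
    if (res_e <= tol_ratio * e0 || res_e == 0.0) break;

    double best_E = -1.0;
    int best_pair = -1, best_u = -1;
    double best_a = 0, best_b = 0;

    for (size_t oi = 0; oi < dict->octs.size(); ++oi) {
      const GaborOctave& oc = dict->octs[oi];
      int s = oc.s;
      int K = oc.pair_hi - oc.pair_lo - 1;
      int C = chunk_cols(s, N);
      ws.ensure((size_t)C * s);
      int s2 = s / 2;
      for (int u0 = 0; u0 < N; u0 += C) {
        int u1 = std::min(u0 + C, N);
        fold_mod_s_packed(residual.memptr(), N, oc.w, oc.T, s, u0, u1, C,
                          ws.re.data(), ws.im.data());
        batch_fft(ws.re.data(), ws.im.data(), C, oc.half);
        for (int k = 0; k <= K; ++k) {
          const GaborPair& pr = dict->pairs[oc.pair_lo + k];
          const double* Pp = pr.P.memptr();
          const double* Qp = pr.Q.memptr();
          const double* Ss = pr.S.memptr();
          // unpack the real-input DFT: bin k of the length-s transform from
          // bins k and s2-k of the packed half-length transform
          int km = (s2 - k) % s2;
          const double* zkr = ws.re.data() + (size_t)(k % s2) * C;
          const double* zki = ws.im.data() + (size_t)(k % s2) * C;
          const double* zmr = ws.re.data() + (size_t)km * C;
          const double* zmi = ws.im.data() + (size_t)km * C;
          double cwr = (k < s / 2) ? oc.full.twr[k] : -1.0;
          double cwi = (k < s / 2) ? oc.full.twi[k] : 0.0;
          for (int u = u0; u < u1; ++u) {
            int uu = u - u0;
            double er = 0.5 * (zkr[uu] + zmr[uu]);
            double ei = 0.5 * (zki[uu] - zmi[uu]);
            double orr = 0.5 * (zki[uu] + zmi[uu]);
            double oi = -0.5 * (zkr[uu] - zmr[uu]);
            double xr = er + cwr * orr - cwi * oi;   // Re DFT[k]
            double xi = ei + cwr * oi + cwi * orr;   // Im DFT[k]
            // Z_k(u) = conj(DFT bin k)
            double a = xr;
            double b = -xi;
            double P = Pp[u], Q = Qp[u], S = Ss[u];
            double E;
            if (k == 0) {
              E = (P > tiny) ? a * a / P : 0.0;
            } else {
              double det = P * Q - S * S;
              if (det <= 1e-12 * (std::fabs(P * Q) + S * S) + tiny) {
                double e1 = (P > tiny) ? a * a / P : 0.0;
                double e2 = (Q > tiny) ? b * b / Q : 0.0;
                E = std::max(e1, e2);
              } else {
                E = (Q * a * a - 2.0 * S * a * b + P * b * b) / det;
              }
            }
            // strict improvement; exact ties break toward lower octave,
            // then lower frequency, then earlier translation
            bool better = E > best_E;
            if (!better && E == best_E && best_pair >= 0) {
              const GaborPair& bp = dict->pairs[best_pair];
              if (pr.j < bp.j ||
                  (pr.j == bp.j && (pr.freq < bp.freq ||
                   (pr.freq == bp.freq && u < best_u)))) {
                better = true;
              }
            }
            if (better) {
              best_E = E; best_pair = oc.pair_lo + k; best_u = u;
              best_a = a; best_b = b;
            }
          }
        }
      }
    }
    if (best_pair < 0 || best_E <= 0.0) break;

    const GaborPair& pr = dict->pairs[best_pair];
    double P = pr.P(best_u), Q = pr.Q(best_u), S = pr.S(best_u);
    double phi;
    if (pr.k == 0) {
      phi = (best_a >= 0) ? 0.0 : M_PI;
    } else {
      double det = P * Q - S * S;
      if (det <= 1e-12 * (std::fabs(P * Q) + S * S) + tiny) {
        double e1 = (P > tiny) ? best_a * best_a / P : 0.0;
        double e2 = (Q > tiny) ? best_b * best_b / Q : 0.0;
        if (e1 >= e2) phi = (best_a >= 0) ? 0.0 : M_PI;
        else phi = (best_b >= 0) ? -M_PI_2 : M_PI_2;
      } else {
        double x1 = (Q * best_a - S * best_b) / det;
        double x2 = (-S * best_a + P * best_b) / det;
        phi = std::atan2(-x2, x1);
      }
    }
    arma::vec g = atom_wave(*dict, pr.oct_idx, pr.freq, best_u, phi);
    double c = arma::dot(residual, g);
    if (c < 0) { phi = wrap_phase(phi + M_PI); c = -c; g = -g; }
    residual -= c * g;

    rec_j.push_back(pr.j);
    rec_f.push_back(pr.freq);
    rec_u.push_back(best_u);
    rec_phi.push_back(wrap_phase(phi));
    rec_c.push_back(c);
    rec_res.push_back(arma::dot(residual, residual));
  }

  int na = rec_j.size();
  NumericMatrix atoms(na, 6);
  colnames(atoms) = CharacterVector::create("iteration", "octave",
      "frequency_hz", "translation", "phase", "coefficient_magnitude");
  for (int i = 0; i < na; ++i) {
    atoms(i, 0) = i;
    atoms(i, 1) = rec_j[i];
    atoms(i, 2) = rec_f[i];
    atoms(i, 3) = rec_u[i];
    atoms(i, 4) = rec_phi[i];
    atoms(i, 5) = rec_c[i];
  }
  return List::create(
      _["atoms"] = atoms,
      _["residual_energies"] = NumericVector(rec_res.begin(), rec_res.end()),
      _["residual"] = NumericVector(residual.begin(), residual.end()),
      _["initial_energy"] = e0);
}

// Direct-form-II-transposed cascade of second-order sections.
// [[Rcpp::export]]
NumericVector sosfilt_cpp(NumericMatrix sos, NumericVector x) {
  int ns = sos.nrow();
  int n = x.size();
  NumericVector y = clone(x);
  for (int s = 0; s < ns; ++s) {
    double b0 = sos(s, 0), b1 = sos(s, 1), b2 = sos(s, 2);
    double a0 = sos(s, 3), a1 = sos(s, 4), a2 = sos(s, 5);
    b0 /= a0; b1 /= a0; b2 /= a0; a1 /= a0; a2 /= a0;
    double z1 = 0.0, z2 = 0.0;
    for (int t = 0; t < n; ++t) {
      double xn = y[t];
      double yn = b0 * xn + z1;
      z1 = b1 * xn + z2 - a1 * yn;
      z2 = b2 * xn - a2 * yn;
      y[t] = yn;
    }
  }
  return y;
}
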