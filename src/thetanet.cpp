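// Computational core: Euler-Maruyama integration of theta-neuron networks
// driven by quenched white-noise input (a random dynamical system), tangent
// dynamics for Lyapunov spectra, and small numeric helpers used by the
// entropy estimators.
//
// Conventions shared with the R side:
//   * phases live on [0,1); a spike is an upward crossing of 1 ~ 0
//   * the quenched input stream is counter-based: increment (i, k) depends
//     only on (seed, neuron i, absolute step k), so slicing a sub-interval
//     of an input realization reproduces the same increments bit-for-bit
//   * coupling matrices arrive in compressed sparse column layout
//     (column j = presynaptic neuron), so a spiking-phase neuron scatters
//     its pulse down one contiguous column

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
#include <cstdint>
#include <vector>
#include <cmath>
#include <algorithm>

using namespace Rcpp;

// ------------------------------------------------------------------ RNG ---

static inline uint64_t splitmix64(uint64_t &x) {
  x += 0x9E3779B97F4A7C15ULL;
  uint64_t z = x;
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

// Marsaglia-Tsang ziggurat (128 layers) on top of splitmix64; used for the
// per-trial independent noise (ensemble burn-in), where speed matters and
// stream slicing is not required.
static uint32_t zig_kn[128];
static double   zig_wn[128], zig_fn[128];
static bool     zig_ready = false;

static void zig_init() {
  double dn = 3.442619855899, tn = dn;
  const double vn = 9.91256303526217e-3, m1 = 2147483648.0;
  double q = vn / std::exp(-0.5 * dn * dn);
  zig_kn[0] = (uint32_t)((dn / q) * m1);
  zig_kn[1] = 0;
  zig_wn[0] = q / m1;
  zig_wn[127] = dn / m1;
  zig_fn[0] = 1.0;
  zig_fn[127] = std::exp(-0.5 * dn * dn);
  for (int i = 126; i >= 1; i--) {
    dn = std::sqrt(-2.0 * std::log(vn / dn + std::exp(-0.5 * dn * dn)));
    zig_kn[i + 1] = (uint32_t)((dn / tn) * m1);
    tn = dn;
    zig_fn[i] = std::exp(-0.5 * dn * dn);
    zig_wn[i] = dn / m1;
  }
  zig_ready = true;
}

struct Rng {
  uint64_t s;
  explicit Rng(uint64_t seed) {
    s = seed ^ 0xD6E8FEB86659FD93ULL;
    for (int i = 0; i < 4; ++i) splitmix64(s);
    if (!zig_ready) zig_init();
  }
  inline uint64_t next64() { return splitmix64(s); }
  inline double unif() { return (next64() >> 11) * (1.0 / 9007199254740992.0); }
  double norm() {
    const double r = 3.442619855899;
    for (;;) {
      int32_t hz = (int32_t)(next64() >> 32);
      uint32_t iz = (uint32_t)hz & 127u;
      uint32_t a = hz < 0 ? (uint32_t)(-(int64_t)hz) : (uint32_t)hz;
      if (a < zig_kn[iz]) return hz * zig_wn[iz];
      if (iz == 0) {
        double x, y;
        do {
          x = -std::log(1.0 - unif()) / r;
          y = -std::log(1.0 - unif());
        } while (y + y < x * x);
        return hz > 0 ? r + x : -(r + x);
      }
      double x = hz * zig_wn[iz];
      if (zig_fn[iz] + unif() * (zig_fn[iz - 1] - zig_fn[iz]) <
          std::exp(-0.5 * x * x))
        return x;
    }
  }
};

// Counter-based standard normal for the quenched input: depends only on
// (seed, neuron, step).  Box-Muller on two splitmix64 outputs.
static inline double qnorm_counter(uint64_t seed, uint64_t i, uint64_t k) {
  uint64_t x = seed ^ (i + 1) * 0xA24BAED4963EE407ULL ^
               (k + 1) * 0x9FB21C651E98DF25ULL;
  uint64_t u = splitmix64(x);
  uint64_t v = splitmix64(x);
  double u1 = (u >> 11) * (1.0 / 9007199254740992.0);
  double u2 = (v >> 11) * (1.0 / 9007199254740992.0);
  double rr = std::sqrt(-2.0 * std::log1p(-u1));
  return rr * std::cos(6.283185307179586476925287 * u2);
}

// ------------------------------------------------- trig lookup on [0,1) ---
// F, Z and their derivatives only need cos/sin of 2*pi*theta; a 4096-entry
// linearly interpolated table has error < 3e-7, far below the Euler step
// error, and removes libm calls from the hot loop.

#define TRIG_TAB 2048
// cos/sin interleaved so one lookup touches a single cache line
static double tab_cs[2 * TRIG_TAB + 4] __attribute__((aligned(64)));
static bool tab_ready = false;
static void tab_init() {
  for (int k = 0; k <= TRIG_TAB; ++k) {
    double th = (double)k / TRIG_TAB;
    tab_cs[2 * k] = std::cos(6.283185307179586476925287 * th);
    tab_cs[2 * k + 1] = std::sin(6.283185307179586476925287 * th);
  }
  tab_ready = true;
}
static inline void sincos01(double th, double &c, double &s) {
  double x = th * TRIG_TAB;
  int k = (int)x;
  double f = x - k;
  const double *p = tab_cs + 2 * k;
  c = p[0] + (p[2] - p[0]) * f;
  s = p[1] + (p[3] - p[1]) * f;
}

// synaptic pulse g of the centered phase offset; scaled so the phase
// integral over the support is 1/2 (a synapse of weight a then delivers
// charge a/4 per presynaptic spike at the traversal speed 2), the scale
// consistent with the published firing-rate operating points
static inline double pulse_g(double x, double b, double d) {
  double u = x / b, t = 1.0 - u * u;
  return (0.5 * d / b) * t * t * t;
}
static inline double pulse_gprime(double x, double b, double d) {
  double u = x / b, t = 1.0 - u * u;
  return -3.0 * u * (d / (b * b)) * t * t;
}

// ------------------------------------------------------------ simulator ---

// Integrates M trials of the N-neuron network for nsteps of size dt from
// absolute time t0 (absolute input-step offset k0).  Noise is either the
// shared quenched input stream (trial_seeds empty) or independent per trial
// (burn-in).  variant: 0 = normal (smooth), 1 = piecewise.
// [[Rcpp::export]]
List cpp_run_trials(NumericMatrix theta0, IntegerVector Ap, IntegerVector Ai,
                    NumericVector Ax, double eta, double eps, double b,
                    double d, double dt, int nsteps, double t0,
                    double input_seed, double k0, IntegerVector trial_seeds,
                    LogicalVector record, bool record_phases, int stride,
                    int variant, double dt_bin) {
  if (!tab_ready) tab_init();
  const int N = theta0.nrow(), M = theta0.ncol();
  const bool shared = trial_seeds.size() == 0;
  const uint64_t iseed = (uint64_t)input_seed;
  const uint64_t koff = (uint64_t)k0;
  const double gamma1 = 1.0 - 2.0 * dt_bin;
  const double sdt = std::sqrt(dt);
  const double ito = 0.5 * eps * eps;

  std::vector<double> th(N * (size_t)M);
  for (int m = 0; m < M; ++m)
    for (int i = 0; i < N; ++i) th[(size_t)m * N + i] = theta0(i, m);

  std::vector<int> sp_trial, sp_neuron;
  std::vector<double> sp_time;
  sp_trial.reserve(1 << 16);
  sp_neuron.reserve(1 << 16);
  sp_time.reserve(1 << 16);

  int nrec = 0;
  NumericVector phases;
  double *ph = nullptr;
  if (record_phases) {
    nrec = nsteps / stride + 1;
    phases = NumericVector((size_t)N * nrec * M);
    phases.attr("dim") = IntegerVector::create(N, nrec, M);
    ph = phases.begin();
  }
  const int *ap = Ap.begin();
  const int *ai = Ai.begin();
  const double *ax = Ax.begin();
  std::vector<char> recmask(N);
  for (int i = 0; i < N; ++i) recmask[i] = record[i] ? 1 : 0;

  std::vector<Rng> trng;
  if (!shared)
    for (int m = 0; m < M; ++m) trng.emplace_back((uint64_t)trial_seeds[m]);

  std::vector<double> noise(N), coup(N, 0.0), tnbuf(N);
  const double ito2pi = ito * 6.283185307179586476925287;
  // per-trial noise buffers are generated inside the trial loop when !shared

  if (!shared && !record_phases) {
    // trial-major traversal: state and RNG stay cache-resident per trial
    for (int m = 0; m < M; ++m) {
      double *x = &th[(size_t)m * N];
      for (int k = 0; k < nsteps; ++k) {
        const double t = t0 + k * dt;
        if (eps != 0.0)
          for (int i = 0; i < N; ++i) noise[i] = trng[m].norm() * sdt;
        for (int j = 0; j < N; ++j) {
          double y = x[j];
          double off = y >= 0.5 ? y - 1.0 : y;
          if (off > -b && off < b) {
            double g = pulse_g(off, b, d);
            for (int idx = ap[j]; idx < ap[j + 1]; ++idx)
              coup[ai[idx]] += ax[idx] * g;
          }
        }
        for (int i = 0; i < N; ++i) {
          double thi = x[i];
          double ci = coup[i];
          coup[i] = 0.0;
          double tn;
          if (variant == 1 && thi >= gamma1) {
            tn = thi + 2.0 * dt;
            if (tn >= 1.0) {
              if (recmask[i]) {
                sp_trial.push_back(m + 1);
                sp_neuron.push_back(i + 1);
                sp_time.push_back(t + (1.0 - thi) * 0.5);
              }
              tn -= 1.0;
            }
          } else {
            double c, s;
            sincos01(thi, c, s);
            double F = 1.0 + c, Z = 1.0 - c, Zp = 6.283185307179586 * s;
            double dth = (F + Z * (ci + eta + ito * Zp)) * dt + Z * eps * noise[i];
            tn = thi + dth;
            if (variant == 1) {
              if (tn >= gamma1 && dth > 0.0) {
                double tau = dt * (gamma1 - thi) / dth;
                tn = gamma1 + 2.0 * (dt - tau);
              } else if (tn < 0.0) {
                tn += 1.0;
              }
            } else {
              if (tn >= 1.0) {
                if (recmask[i]) {
                  sp_trial.push_back(m + 1);
                  sp_neuron.push_back(i + 1);
                  sp_time.push_back(t + dt * (1.0 - thi) / dth);
                }
                tn -= 1.0;
                if (tn >= 1.0) tn = tn - std::floor(tn);
              } else if (tn < 0.0) {
                tn += 1.0;
              }
            }
          }
          x[i] = tn;
        }
        if ((k & 1023) == 0) {
          if (!std::isfinite(x[0]))
            stop("integration diverged (non-finite state) in trial %d near t = %g",
                 m + 1, t);
          Rcpp::checkUserInterrupt();
        }
      }
    }
    NumericMatrix thF(N, M);
    for (int m = 0; m < M; ++m)
      for (int i = 0; i < N; ++i) thF(i, m) = th[(size_t)m * N + i];
    return List::create(
        _["trial"] = IntegerVector(sp_trial.begin(), sp_trial.end()),
        _["neuron"] = IntegerVector(sp_neuron.begin(), sp_neuron.end()),
        _["time"] = NumericVector(sp_time.begin(), sp_time.end()),
        _["theta_final"] = thF);
  }

  for (int k = 0; k < nsteps; ++k) {
    const double t = t0 + k * dt;
    if (record_phases && k % stride == 0) {
      int r = k / stride;
      for (int m = 0; m < M; ++m)
        for (int i = 0; i < N; ++i)
          ph[(size_t)m * N * nrec + (size_t)r * N + i] = th[(size_t)m * N + i];
    }
    if (shared && eps != 0.0) {
      for (int i = 0; i < N; ++i)
        noise[i] = qnorm_counter(iseed, (uint64_t)i, koff + k) * sdt;
    }
    for (int m = 0; m < M; ++m) {
      double *x = &th[(size_t)m * N];
      if (!shared && eps != 0.0)
        for (int i = 0; i < N; ++i) noise[i] = trng[m].norm() * sdt;
      // presynaptic pulse scatter (coup holds Sum_j a_ij g(theta_j))
      for (int j = 0; j < N; ++j) {
        double y = x[j];
        double off = y >= 0.5 ? y - 1.0 : y;
        if (off > -b && off < b) {
          double g = pulse_g(off, b, d);
          for (int idx = ap[j]; idx < ap[j + 1]; ++idx)
            coup[ai[idx]] += ax[idx] * g;
        }
      }
      if (variant == 0) {
        // branch-free compute pass, then a cheap scalar wrap/spike pass
        double *tn = tnbuf.data();
        for (int i = 0; i < N; ++i) {
          double thi = x[i];
          double xx = thi * TRIG_TAB;
          int kk = (int)xx;
          double f = xx - kk;
          const double *p = tab_cs + 2 * kk;
          double c = p[0] + (p[2] - p[0]) * f;
          double s = p[1] + (p[3] - p[1]) * f;
          double Z = 1.0 - c;
          double ci = coup[i];
          coup[i] = 0.0;
          tn[i] = thi + ((1.0 + c) + Z * (ci + eta + ito2pi * s)) * dt +
                  Z * eps * noise[i];
        }
        for (int i = 0; i < N; ++i) {
          double w = tn[i];
          if (w >= 1.0) {
            if (recmask[i]) {
              sp_trial.push_back(m + 1);
              sp_neuron.push_back(i + 1);
              sp_time.push_back(t + dt * (1.0 - x[i]) / (w - x[i]));
            }
            w -= 1.0;
            if (w >= 1.0) w -= std::floor(w);
          } else if (w < 0.0) {
            w += 1.0;
          }
          x[i] = w;
        }
        continue;
      }
      for (int i = 0; i < N; ++i) {
        double thi = x[i];
        double ci = coup[i];
        coup[i] = 0.0;  // reset-on-read keeps the buffer clean
        double tn;
        if (variant == 1 && thi >= gamma1) {
          // piecewise branch: constant speed 2, insensitive to all input
          tn = thi + 2.0 * dt;
          if (tn >= 1.0) {
            if (recmask[i]) {
              sp_trial.push_back(m + 1);
              sp_neuron.push_back(i + 1);
              sp_time.push_back(t + (1.0 - thi) * 0.5);
            }
            tn -= 1.0;
          }
        } else {
          double c, s;
          sincos01(thi, c, s);
          double F = 1.0 + c, Z = 1.0 - c, Zp = 6.283185307179586 * s;
          double dth = (F + Z * (ci + eta + ito * Zp)) * dt + Z * eps * noise[i];
          tn = thi + dth;
          if (variant == 1) {
            if (tn >= gamma1 && dth > 0.0) {
              // crossed into [1-2*dt_bin, 1): finish the step at speed 2 so
              // the partition spiking rule holds exactly
              double tau = dt * (gamma1 - thi) / dth;
              tn = gamma1 + 2.0 * (dt - tau);
            } else if (tn < 0.0) {
              tn += 1.0;
            }
          } else {
            if (tn >= 1.0) {
              if (recmask[i]) {
                sp_trial.push_back(m + 1);
                sp_neuron.push_back(i + 1);
                sp_time.push_back(t + dt * (1.0 - thi) / dth);
              }
              tn -= 1.0;
              if (tn >= 1.0) tn = tn - std::floor(tn);
            } else if (tn < 0.0) {
              tn += 1.0;
            }
          }
        }
        x[i] = tn;
      }
    }
    if ((k & 1023) == 0) {
      for (int m = 0; m < M; ++m) {
        double v = th[(size_t)m * N];
        if (!std::isfinite(v))
          stop("integration diverged (non-finite state) in trial %d near t = %g",
               m + 1, t);
      }
      Rcpp::checkUserInterrupt();
    }
  }

  if (record_phases && nsteps % stride == 0) {
    int r = nsteps / stride;
    for (int m = 0; m < M; ++m)
      for (int i = 0; i < N; ++i)
        ph[(size_t)m * N * nrec + (size_t)r * N + i] = th[(size_t)m * N + i];
  }
  NumericMatrix thFinal(N, M);
  for (int m = 0; m < M; ++m)
    for (int i = 0; i < N; ++i) thFinal(i, m) = th[(size_t)m * N + i];

  List out = List::create(
      _["trial"] = IntegerVector(sp_trial.begin(), sp_trial.end()),
      _["neuron"] = IntegerVector(sp_neuron.begin(), sp_neuron.end()),
      _["time"] = NumericVector(sp_time.begin(), sp_time.end()),
      _["theta_final"] = thFinal);
  if (record_phases) out["phases"] = phases;
  return out;
}

// Single isolated cell with a precomputed per-step synaptic drive (replayed
// or surrogate presynaptic trains already convolved with the pulse) and a
// precomputed quenched noise path (dW per step).
// [[Rcpp::export]]
List cpp_run_cell(double theta0, double eta, double eps, double b, double d,
                  double dt, int nsteps, double t0, NumericVector noise,
                  NumericVector drive, int variant, double dt_bin) {
  if (!tab_ready) tab_init();
  const double gamma1 = 1.0 - 2.0 * dt_bin;
  const double ito = 0.5 * eps * eps;
  const double *nz = noise.begin();
  const double *dr = drive.begin();
  double x = theta0;
  std::vector<double> sp_time;
  for (int k = 0; k < nsteps; ++k) {
    const double t = t0 + k * dt;
    double tn;
    if (variant == 1 && x >= gamma1) {
      tn = x + 2.0 * dt;
      if (tn >= 1.0) {
        sp_time.push_back(t + (1.0 - x) * 0.5);
        tn -= 1.0;
      }
    } else {
      double c, s;
      sincos01(x, c, s);
      double F = 1.0 + c, Z = 1.0 - c, Zp = 6.283185307179586 * s;
      double dth = (F + Z * (dr[k] + eta + ito * Zp)) * dt + Z * eps * nz[k];
      tn = x + dth;
      if (variant == 1) {
        if (tn >= gamma1 && dth > 0.0) {
          double tau = dt * (gamma1 - x) / dth;
          tn = gamma1 + 2.0 * (dt - tau);
        } else if (tn < 0.0) {
          tn += 1.0;
        }
      } else {
        if (tn >= 1.0) {
          sp_time.push_back(t + dt * (1.0 - x) / dth);
          tn -= 1.0;
        } else if (tn < 0.0) {
          tn += 1.0;
        }
      }
    }
    if (!std::isfinite(tn)) stop("integration diverged near t = %g", t);
    x = tn;
  }
  return List::create(_["time"] = NumericVector(sp_time.begin(), sp_time.end()),
                      _["theta_final"] = x);
}

// Accumulate  Sum_spikes w * p(t - s)  with p(tau) = g(2*tau - b) on [0, b]
// into a per-step drive array (constant-velocity replay of the pulse).
// [[Rcpp::export]]
NumericVector cpp_pulse_drive(NumericVector times, NumericVector weights,
                              double b, double d, double dt, int nsteps,
                              double t0) {
  NumericVector drive(nsteps);
  const int nsp = times.size();
  for (int q = 0; q < nsp; ++q) {
    double s = times[q] - t0;
    double w = weights[q];
    int kmin = (int)std::ceil(s / dt);
    if (kmin < 0) kmin = 0;
    int kmax = (int)std::floor((s + b) / dt);
    if (kmax > nsteps - 1) kmax = nsteps - 1;
    for (int k = kmin; k <= kmax; ++k) {
      double tau = k * dt - s;
      double xarg = 2.0 * tau - b;
      if (xarg > -b && xarg < b) drive[k] += w * pulse_g(xarg, b, d);
    }
  }
  return drive;
}

// ------------------------------------------------------------- Lyapunov ---

// Tangent dynamics of the Euler-Maruyama map with QR re-orthonormalization.
// Returns exponents in nats per time-unit plus a convergence trace.
// [[Rcpp::export]]
List cpp_lyapunov(NumericVector theta0, IntegerVector Ap, IntegerVector Ai,
                  NumericVector Ax, double eta, double eps, double b, double d,
                  double dt, int nsteps, int ntrans, int m, int ortho_steps,
                  double input_seed, double k0, double q_seed, int variant,
                  double dt_bin) {
  if (!tab_ready) tab_init();
  const int N = theta0.size();
  const uint64_t iseed = (uint64_t)input_seed;
  const uint64_t koff = (uint64_t)k0;
  const double gamma1 = 1.0 - 2.0 * dt_bin;
  const double sdt = std::sqrt(dt);
  const double ito = 0.5 * eps * eps;
  const double twopi = 6.283185307179586476925287;

  arma::vec x(N);
  for (int i = 0; i < N; ++i) x[i] = theta0[i];
  const int *ap = Ap.begin();
  const int *ai = Ai.begin();
  const double *ax = Ax.begin();

  // random orthonormal initial frame, Qt is m x N (columns contiguous per
  // neuron so the sparse Jacobian scatter works on contiguous memory)
  Rng qr_rng((uint64_t)q_seed);
  arma::mat Q0(N, m);
  for (int j = 0; j < m; ++j)
    for (int i = 0; i < N; ++i) Q0(i, j) = qr_rng.norm();
  arma::mat Qn, Rn;
  arma::qr_econ(Qn, Rn, Q0);
  arma::mat Qt = Qn.t();          // m x N
  arma::mat Qold(m, N);

  arma::vec lsum(m, arma::fill::zeros);
  std::vector<double> trace;      // running estimates, every ortho after trans
  std::vector<double> diagR_last(m);
  double t_accum = 0.0;

  std::vector<double> noise(N), coup(N, 0.0), Zv(N), Dv(N);
  std::vector<int> sup_j;
  std::vector<double> sup_gp;
  sup_j.reserve(64);
  sup_gp.reserve(64);

  int n_ortho_trace = 0;
  for (int k = 0; k < nsteps; ++k) {
    for (int i = 0; i < N; ++i)
      noise[i] = qnorm_counter(iseed, (uint64_t)i, koff + k) * sdt;

    // pulse pass: coupling field and in-support presynaptic derivative list
    sup_j.clear();
    sup_gp.clear();
    for (int j = 0; j < N; ++j) {
      double y = x[j];
      double off = y >= 0.5 ? y - 1.0 : y;
      if (off > -b && off < b) {
        double g = pulse_g(off, b, d);
        for (int idx = ap[j]; idx < ap[j + 1]; ++idx)
          coup[ai[idx]] += ax[idx] * g;
        sup_j.push_back(j);
        sup_gp.push_back(pulse_gprime(off, b, d));
      }
    }

    // state update + diagonal of the step Jacobian
    for (int i = 0; i < N; ++i) {
      double thi = x[i];
      double ci = coup[i];
      coup[i] = 0.0;
      if (variant == 1 && thi >= gamma1) {
        Zv[i] = 0.0;
        Dv[i] = 1.0;
        double tn = thi + 2.0 * dt;
        if (tn >= 1.0) tn -= 1.0;
        x[i] = tn;
      } else {
        double c, s;
        sincos01(thi, c, s);
        double F = 1.0 + c, Z = 1.0 - c;
        double Fp = -twopi * s, Zp = twopi * s, Zpp = twopi * twopi * c;
        double dr = ci + eta + ito * Zp;
        double dth = (F + Z * dr) * dt + Z * eps * noise[i];
        Zv[i] = Z;
        Dv[i] = 1.0 + dt * (Fp + Zp * dr + Z * ito * Zpp) + eps * Zp * noise[i];
        double tn = thi + dth;
        if (variant == 1) {
          if (tn >= gamma1 && dth > 0.0) {
            double tau = dt * (gamma1 - thi) / dth;
            tn = gamma1 + 2.0 * (dt - tau);
          } else if (tn < 0.0) {
            tn += 1.0;
          }
        } else {
          if (tn >= 1.0) tn -= 1.0;
          else if (tn < 0.0) tn += 1.0;
        }
        x[i] = tn;
      }
    }

    // tangent update: Qt_new = diag part + coupling cross terms
    Qold = Qt;
    for (int i = 0; i < N; ++i) Qt.col(i) = Dv[i] * Qold.col(i);
    for (size_t q = 0; q < sup_j.size(); ++q) {
      int j = sup_j[q];
      double gp = sup_gp[q];
      for (int idx = ap[j]; idx < ap[j + 1]; ++idx) {
        int i = ai[idx];
        double coef = dt * ax[idx] * gp * Zv[i];
        if (coef != 0.0) Qt.col(i) += coef * Qold.col(j);
      }
    }

    if ((k + 1) % ortho_steps == 0) {
      arma::mat Qmat = Qt.t();
      arma::mat QQ, RR;
      if (!arma::qr_econ(QQ, RR, Qmat))
        stop("QR re-orthonormalization failed at step %d", k + 1);
      Qt = QQ.t();
      if (k + 1 > ntrans) {
        for (int j = 0; j < m; ++j) {
          double rjj = std::abs(RR(j, j));
          if (rjj <= 0.0 || !std::isfinite(rjj))
            stop("degenerate R diagonal (index %d) at step %d", j + 1, k + 1);
          lsum[j] += std::log(rjj);
          diagR_last[j] = rjj;
        }
        t_accum += ortho_steps * dt;
        ++n_ortho_trace;
        for (int j = 0; j < m; ++j) trace.push_back(lsum[j] / t_accum);
      }
      Rcpp::checkUserInterrupt();
    }
  }

  if (t_accum <= 0.0) stop("no post-transient accumulation; increase nsteps");
  NumericVector lambda(m);
  for (int j = 0; j < m; ++j) lambda[j] = lsum[j] / t_accum;
  NumericMatrix tr(m, n_ortho_trace);
  for (int c = 0; c < n_ortho_trace; ++c)
    for (int j = 0; j < m; ++j) tr(j, c) = trace[(size_t)c * m + j];
  return List::create(_["lambda"] = lambda, _["trace"] = tr,
                      _["t_accum"] = t_accum);
}

// ------------------------------------------------------- entropy helper ---

// Plug-in entropy (bits per word) of every column of an id matrix
// (rows = trials, columns = time windows).
// [[Rcpp::export]]
NumericVector cpp_word_entropies(NumericMatrix ids) {
  const int n = ids.nrow(), W = ids.ncol();
  NumericVector H(W);
  const double log2inv = 1.0 / std::log(2.0);
  // word ids are small non-negative integers (< 2^(K*L)); when they fit a
  // modest table, count with touched-entry reset, otherwise sort
  double mx = 0.0;
  bool integral = true;
  for (int w = 0; w < W && integral; ++w)
    for (int r = 0; r < n; ++r) {
      double v = ids(r, w);
      if (v < 0 || v != std::floor(v)) { integral = false; break; }
      if (v > mx) mx = v;
    }
  if (integral && mx < 4194304.0) {
    std::vector<int> cnt((size_t)mx + 1, 0);
    std::vector<int> touched;
    touched.reserve(n);
    for (int w = 0; w < W; ++w) {
      touched.clear();
      for (int r = 0; r < n; ++r) {
        int v = (int)ids(r, w);
        if (cnt[v]++ == 0) touched.push_back(v);
      }
      double h = 0.0;
      for (int v : touched) {
        double p = (double)cnt[v] / n;
        h -= p * std::log(p) * log2inv;
        cnt[v] = 0;
      }
      H[w] = h;
    }
  } else {
    std::vector<double> buf(n);
    for (int w = 0; w < W; ++w) {
      for (int r = 0; r < n; ++r) buf[r] = ids(r, w);
      std::sort(buf.begin(), buf.end());
      double h = 0.0;
      int r = 0;
      while (r < n) {
        int r2 = r + 1;
        while (r2 < n && buf[r2] == buf[r]) ++r2;
        double p = (double)(r2 - r) / n;
        h -= p * std::log(p) * log2inv;
        r = r2;
      }
      H[w] = h;
    }
  }
  return H;
}

// Quenched input increments for neurons (0-based) over absolute steps
// [k0, k0 + nk); returns an nk x length(neurons) matrix of dW values.
// [[Rcpp::export]]
NumericMatrix cpp_input_increments(double input_seed, IntegerVector neurons,
                                   double k0, int nk, double dt) {
  const uint64_t iseed = (uint64_t)input_seed;
  const uint64_t koff = (uint64_t)k0;
  const double sdt = std::sqrt(dt);
  NumericMatrix out(nk, neurons.size());
  for (int j = 0; j < neurons.size(); ++j)
    for (int k = 0; k < nk; ++k)
      out(k, j) = qnorm_counter(iseed, (uint64_t)neurons[j], koff + k) * sdt;
  return out;
}

// Entropy curve straight from spike lists: for each word length L, scatter
// spikes into per-(trial, window) word ids (bitwise OR reproduces the
// clipped binarization) and accumulate plug-in entropies by counting.
// Returns bits per word per window mean; the R side normalizes by L*dt.
// [[Rcpp::export]]
List cpp_spike_entropy_curve(IntegerVector trial, IntegerVector bin,
                             IntegerVector cell, int M, int nbins, int K,
                             IntegerVector Ls) {
  const int nL = Ls.size(), nsp = trial.size();
  NumericVector H(nL);
  IntegerVector wins(nL);
  const double log2inv = 1.0 / std::log(2.0);
  int maxbits = 0;
  for (int li = 0; li < nL; ++li) maxbits = std::max(maxbits, K * Ls[li]);
  if (maxbits > 22) stop("K*L too large for the counting table");
  std::vector<int> cnt((size_t)1 << maxbits, 0);
  std::vector<int> ids;
  std::vector<int> touched;
  touched.reserve(M);
  for (int li = 0; li < nL; ++li) {
    const int L = Ls[li];
    const int nwin = nbins / L;
    wins[li] = nwin;
    if (nwin == 0) {
      H[li] = NA_REAL;
      continue;
    }
    ids.assign((size_t)M * nwin, 0);
    for (int q = 0; q < nsp; ++q) {
      int b = bin[q];
      int w = b / L;
      if (w >= nwin) continue;
      int pos = b - w * L;
      int shift = (K - 1 - cell[q]) * L + (L - 1 - pos);
      ids[(size_t)w * M + (trial[q] - 1)] |= (1 << shift);
    }
    double hsum = 0.0;
    for (int w = 0; w < nwin; ++w) {
      const int *col = &ids[(size_t)w * M];
      touched.clear();
      for (int m = 0; m < M; ++m) {
        int v = col[m];
        if (cnt[v]++ == 0) touched.push_back(v);
      }
      double h = 0.0;
      for (int v : touched) {
        double p = (double)cnt[v] / M;
        h -= p * std::log(p) * log2inv;
        cnt[v] = 0;
      }
      hsum += h;
    }
    H[li] = hsum / nwin;
    Rcpp::checkUserInterrupt();
  }
  return List::create(_["H"] = H, _["windows"] = wins);
}
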