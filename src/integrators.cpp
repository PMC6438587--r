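#include <Rcpp.h>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

// Euler-Maruyama integrators for the stochastic neural field and for the
// reduced phase equations.  Time is integrated in units of the membrane
// time constant tau.  Randomness comes from a self-contained
// xoshiro256++ generator seeded explicitly by the R wrappers (R's
// inversion-method normal sampler is several times slower and dominates
// the cost of the field integration), so trajectories are
// bitwise-reproducible given the seed.

namespace {

struct Xoshiro {
  uint64_t s[4];
  explicit Xoshiro(uint64_t seed) {
    // splitmix64 expansion of the seed
    for (int i = 0; i < 4; ++i) {
      seed += 0x9e3779b97f4a7c15ULL;
      uint64_t z = seed;
      z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
      z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
      s[i] = z ^ (z >> 31);
    }
  }
  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  inline uint64_t next() {
    const uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    const uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return result;
  }
  inline double unif() {  // (0, 1)
    return ((next() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
  // Marsaglia-Tsang ziggurat for the standard normal (128 layers);
  // falls back to the analytic tail beyond r.  Tables are shared and
  // built once.
  static double zig_x[129], zig_y[129];
  static bool zig_ready;
  static void zig_init() {
    const double r = 3.442619855899;       // right edge of the base layer
    const double v = 9.91256303526217e-3;  // area of each layer
    double f = std::exp(-0.5 * r * r);
    zig_x[0] = v / f;  // pseudo edge so layer 0 has area v
    zig_x[1] = r;
    zig_y[0] = f;      // density at r (layer 0 cap)
    for (int i = 2; i < 128; ++i) {
      zig_x[i] = std::sqrt(-2.0 * std::log(v / zig_x[i - 1] +
                                           std::exp(-0.5 * zig_x[i - 1] *
                                                    zig_x[i - 1])));
    }
    zig_x[128] = 0.0;
    for (int i = 1; i <= 128; ++i)
      zig_y[i] = std::exp(-0.5 * zig_x[i] * zig_x[i]);
    zig_ready = true;
  }
  inline double norm() {
    if (!zig_ready) zig_init();
    for (;;) {
      uint64_t bits = next();
      int idx = (int)(bits & 127u);
      double sign = (bits & 128u) ? -1.0 : 1.0;
      double u = (((bits >> 11) + 0.5) * (1.0 / 9007199254740992.0));
      double x = u * zig_x[idx];
      if (x < zig_x[idx + 1]) return sign * x;
      if (idx == 0) {
        // tail sampling beyond r (Marsaglia's method)
        const double r = 3.442619855899;
        double xx, yy;
        do {
          xx = -std::log(unif()) / r;
          yy = -std::log(unif());
        } while (yy + yy < xx * xx);
        return sign * (r + xx);
      }
      double y0 = zig_y[idx], y1 = zig_y[idx + 1];
      if (y0 + unif() * (y1 - y0) < std::exp(-0.5 * x * x))
        return sign * x;
    }
  }
};

double Xoshiro::zig_x[129];
double Xoshiro::zig_y[129];
bool Xoshiro::zig_ready = false;

inline double sigmoid(double u, double gain, double thr, double f0) {
  return f0 / (1.0 + std::exp(-gain * (u - thr)));
}

inline double wrap_pi(double x) {
  // floor-based wrap to [-pi, pi); avoids fmod on purpose (symbol
  // versioning headaches across glibc builds)
  return x - 2.0 * M_PI * std::floor((x + M_PI) / (2.0 * M_PI));
}

}  // namespace

// [[Rcpp::export]]
List field_euler_cpp(NumericMatrix u0,
                     NumericVector jbar, NumericVector gain,
                     NumericVector thr, NumericVector f0,
                     NumericVector hbar, NumericVector hbias,
                     double epsilon, double a, double b,
                     int coupling_model,           // 0 none, 1 A, 2 B
                     NumericVector e_unif, NumericVector kbar,
                     double dt, int n_steps, int save_every,
                     int snapshot_every, bool noise_on, double seed) {
  const int n = u0.nrow();
  const int m = u0.ncol();
  const double dtheta = 2.0 * M_PI / n;
  // weak-noise scaling: the noise term is sqrt(2)*epsilon*dW, i.e. the
  // same order epsilon as the stimulus and coupling drives, so that the
  // stationary phase concentration is kappa = hbar/(eps*A*D)
  const double noise_amp = std::sqrt(2.0) * epsilon;
  const double sd_white = std::sqrt(a * dt / dtheta);
  const double sd_cos = std::sqrt(b * dt);
  Xoshiro rng((uint64_t)seed);

  std::vector<double> ct(n), st(n);
  for (int i = 0; i < n; ++i) {
    double th = -M_PI + i * dtheta;
    ct[i] = std::cos(th);
    st[i] = std::sin(th);
  }

  // stimulus drive eps * hbar * cos(theta - hbias), fixed in time
  std::vector< std::vector<double> > hdrive(m, std::vector<double>(n));
  for (int j = 0; j < m; ++j)
    for (int i = 0; i < n; ++i)
      hdrive[j][i] = hbar[j] * (ct[i] * std::cos(hbias[j]) +
                                st[i] * std::sin(hbias[j]));

  std::vector< std::vector<double> > u(m, std::vector<double>(n));
  for (int j = 0; j < m; ++j)
    for (int i = 0; i < n; ++i) u[j][i] = u0(i, j);

  const int n_save = n_steps / save_every + 1;
  NumericMatrix phases(n_save, m), amps(n_save, m);
  NumericVector phase_times(n_save);
  const int n_snap = snapshot_every > 0 ? n_steps / snapshot_every + 1 : 0;
  NumericVector snapshots(n_snap > 0 ? (R_xlen_t)n * m * n_snap : 0);
  NumericVector snap_times(n_snap);

  std::vector< std::vector<double> > fu(m, std::vector<double>(n));
  std::vector<double> cmom(m), smom(m), mmom(m);
  int i_save = 0, i_snap = 0;

  for (int step = 0; step <= n_steps; ++step) {
    if (step % save_every == 0 && i_save < n_save) {
      for (int j = 0; j < m; ++j) {
        double zre = 0.0, zim = 0.0;
        for (int i = 0; i < n; ++i) {
          if (!std::isfinite(u[j][i]))
            stop("field blow-up (non-finite activity) at t = %g", step * dt);
          zre += u[j][i] * ct[i];
          zim += u[j][i] * st[i];
        }
        double amp = std::sqrt(zre * zre + zim * zim) * dtheta / M_PI;
        amps(i_save, j) = amp;
        phases(i_save, j) = (amp < 1e-8) ? NA_REAL : -std::atan2(zim, zre);
      }
      phase_times[i_save] = step * dt;
      ++i_save;
    }
    if (n_snap > 0 && step % snapshot_every == 0 && i_snap < n_snap) {
      for (int j = 0; j < m; ++j)
        for (int i = 0; i < n; ++i)
          snapshots[(R_xlen_t)i_snap * n * m + (R_xlen_t)j * n + i] = u[j][i];
      snap_times[i_snap] = step * dt;
      ++i_snap;
    }
    if (step == n_steps) break;

    for (int j = 0; j < m; ++j) {
      double c = 0.0, s = 0.0, tot = 0.0;
      for (int i = 0; i < n; ++i) {
        fu[j][i] = sigmoid(u[j][i], gain[j], thr[j], f0[j]);
        c += ct[i] * fu[j][i];
        s += st[i] * fu[j][i];
        tot += fu[j][i];
      }
      cmom[j] = c * dtheta;
      smom[j] = s * dtheta;
      mmom[j] = tot * dtheta;
    }

    for (int j = 0; j < m; ++j) {
      const int o = (m == 2) ? 1 - j : j;
      double z1 = 0.0, z2 = 0.0;
      if (noise_on && b > 0) { z1 = rng.norm(); z2 = rng.norm(); }
      for (int i = 0; i < n; ++i) {
        double drift = -u[j][i] + jbar[j] * (cmom[j] * ct[i] + smom[j] * st[i]);
        if (coupling_model == 1 && m == 2)
          drift += epsilon * (e_unif[j] * mmom[o] +
                              kbar[j] * (cmom[o] * ct[i] + smom[o] * st[i]));
        else if (coupling_model == 2 && m == 2)
          drift += epsilon * kbar[j] * fu[o][i];  // delta kernel acts pointwise
        drift += epsilon * hdrive[j][i];
        double du = dt * drift;
        if (noise_on) {
          double dW = 0.0;
          if (a > 0) dW += sd_white * rng.norm();
          if (b > 0) dW += sd_cos * (z1 * ct[i] + z2 * st[i]);
          du += noise_amp * dW;
        }
        u[j][i] += du;
      }
    }
  }

  List out = List::create(_["phases"] = phases, _["amps"] = amps,
                          _["phase_times"] = phase_times);
  if (n_snap > 0) {
    snapshots.attr("dim") = IntegerVector::create(n, m, n_snap);
    out["snapshots"] = snapshots;
    out["snap_times"] = snap_times;
  }
  return out;
}

// [[Rcpp::export]]
List phase_sde_cpp(NumericVector beta0,
                   NumericVector lambda, NumericVector diffusion,
                   NumericVector theta_bar, double epsilon,
                   int coupling_model,            // 0 none, 1 sine, 2 table
                   NumericVector k_amp,
                   NumericVector k_values,        // table on [-pi, pi)
                   double dt, int n_steps, int save_every, double seed) {
  const int m = beta0.size();
  Xoshiro rng((uint64_t)seed);
  std::vector<double> beta(m), unwrapped(m), sd(m);
  for (int j = 0; j < m; ++j) {
    beta[j] = beta0[j];
    unwrapped[j] = beta0[j];
    // matches the field's sqrt(2)*epsilon noise scaling: phase diffusion
    // coefficient is epsilon^2 * D
    sd[j] = std::sqrt(2.0 * diffusion[j] * dt) * epsilon;
  }
  const int ntab = k_values.size();
  const double dtab = ntab > 0 ? 2.0 * M_PI / ntab : 0.0;

  const int n_save = n_steps / save_every + 1;
  NumericMatrix wrapped_out(n_save, m), unwrapped_out(n_save, m);
  NumericVector times(n_save);
  int i_save = 0;

  for (int step = 0; step <= n_steps; ++step) {
    if (step % save_every == 0 && i_save < n_save) {
      for (int j = 0; j < m; ++j) {
        wrapped_out(i_save, j) = wrap_pi(beta[j]);
        unwrapped_out(i_save, j) = unwrapped[j];
      }
      times[i_save] = step * dt;
      ++i_save;
    }
    if (step == n_steps) break;

    double incr[2] = {0.0, 0.0};
    for (int j = 0; j < m; ++j) {
      const int o = (m == 2) ? 1 - j : j;
      double drift = -epsilon * lambda[j] * std::sin(beta[j] + theta_bar[j]);
      if (coupling_model != 0 && m == 2) {
        double x = wrap_pi(beta[j] - beta[o]);
        double K;
        if (coupling_model == 1) {
          K = k_amp[j] * std::sin(x);
        } else {
          // periodic linear interpolation on the equispaced table
          double pos = (x + M_PI) / dtab;
          int i0 = (int)std::floor(pos);
          double frac = pos - i0;
          int i1 = (i0 + 1) % ntab;
          i0 = i0 % ntab;
          K = (1.0 - frac) * k_values[i0] + frac * k_values[i1];
        }
        drift -= epsilon * K;
      }
      incr[j] = drift * dt + sd[j] * rng.norm();
    }
    for (int j = 0; j < m; ++j) {
      beta[j] = wrap_pi(beta[j] + incr[j]);
      unwrapped[j] += incr[j];
    }
  }

  return List::create(_["wrapped"] = wrapped_out,
                      _["unwrapped"] = unwrapped_out,
                      _["times"] = times);
}
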