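// Brownian dynamics engine for a surface-tethered bead-spring chain in
// linear shear flow, in reduced units (lengths in a, energies in kBT,
// times in tau0 = zeta a^2 / kBT).  Euler-Maruyama with Gaussian impulses
// of variance 2*dt per bead per axis per step.
//
// The RNG is a self-contained xoshiro256++ stream seeded via splitmix64,
// with a 128-level ziggurat normal sampler; both are standard published
// algorithms.  Determinism contract: the impulse stream is a pure function
// of the seed.

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <vector>

#if defined(__GNUC__) && !defined(__clang__)
#pragma GCC optimize("O3")
#endif

using namespace Rcpp;

// ---------------------------------------------------------------------------
// RNG: splitmix64 seeding + xoshiro256++
// ---------------------------------------------------------------------------

struct Rng {
  uint64_t s[4];
  uint32_t spare;
  bool has_spare;

  explicit Rng(uint64_t seed) : spare(0), has_spare(false) {
    uint64_t x = seed;
    for (int i = 0; i < 4; ++i) {
      // splitmix64
      x += 0x9E3779B97F4A7C15ULL;
      uint64_t z = x;
      z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
      z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
      s[i] = z ^ (z >> 31);
    }
  }

  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }

  inline uint64_t next_u64() {
    uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0];
    s[3] ^= s[1];
    s[1] ^= s[2];
    s[0] ^= s[3];
    s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return result;
  }

  // both halves of each 64-bit draw are used
  inline uint32_t next_u32() {
    if (has_spare) {
      has_spare = false;
      return spare;
    }
    uint64_t v = next_u64();
    spare = (uint32_t)v;
    has_spare = true;
    return (uint32_t)(v >> 32);
  }

  // uniform in (0,1), never exactly 0 or 1
  inline double unif() {
    return ((double)next_u32() + 0.5) * 2.3283064365386963e-10;
  }
};

// ---------------------------------------------------------------------------
// 128-level ziggurat for the standard normal (Marsaglia-Tsang construction)
// ---------------------------------------------------------------------------

struct Ziggurat {
  uint32_t kn[128];
  double wn[128], fn[128];

  Ziggurat() {
    const double m1 = 2147483648.0;  // 2^31
    double dn = 3.442619855899, tn = dn;
    const double vn = 9.91256303526217e-3;
    double q = vn / std::exp(-0.5 * dn * dn);
    kn[0] = (uint32_t)((dn / q) * m1);
    kn[1] = 0;
    wn[0] = q / m1;
    wn[127] = dn / m1;
    fn[0] = 1.0;
    fn[127] = std::exp(-0.5 * dn * dn);
    for (int i = 126; i >= 1; i--) {
      dn = std::sqrt(-2.0 * std::log(vn / dn + std::exp(-0.5 * dn * dn)));
      kn[i + 1] = (uint32_t)((dn / tn) * m1);
      tn = dn;
      fn[i] = std::exp(-0.5 * dn * dn);
      wn[i] = dn / m1;
    }
  }
};

static const Ziggurat ZIG;

static inline double rnorm_zig(Rng& rng) {
  const double rtail = 3.442619855899;
  for (;;) {
    int32_t hz = (int32_t)rng.next_u32();
    uint32_t iz = (uint32_t)hz & 127u;
    uint32_t az = hz < 0 ? (uint32_t)(-(int64_t)hz) : (uint32_t)hz;
    if (az < ZIG.kn[iz]) return hz * ZIG.wn[iz];
    // slow path
    for (;;) {
      double x = hz * ZIG.wn[iz];
      if (iz == 0) {  // tail
        double y;
        do {
          x = -std::log(rng.unif()) / rtail;
          y = -std::log(rng.unif());
        } while (y + y < x * x);
        return hz > 0 ? rtail + x : -(rtail + x);
      }
      if (ZIG.fn[iz] + rng.unif() * (ZIG.fn[iz - 1] - ZIG.fn[iz]) <
          std::exp(-0.5 * x * x))
        return x;
      hz = (int32_t)rng.next_u32();
      iz = (uint32_t)hz & 127u;
      az = hz < 0 ? (uint32_t)(-(int64_t)hz) : (uint32_t)hz;
      if (az < ZIG.kn[iz]) return hz * ZIG.wn[iz];
    }
  }
}

// [[Rcpp::export]]
NumericMatrix draw_noise_cpp(int n_beads, double dt, double seed, int n_steps) {
  if (dt <= 0) stop("dt must be positive");
  Rng rng((uint64_t)seed);
  double sd = std::sqrt(2.0 * dt);
  NumericMatrix out(n_steps * n_beads, 3);
  for (int i = 0; i < n_steps * n_beads; ++i)
    for (int v = 0; v < 3; ++v) out(i, v) = sd * rnorm_zig(rng);
  return out;
}

// ---------------------------------------------------------------------------
// Force kernels.  pos is (N+1) x 3; bead 0 is the tether.
// Forces are *reported* for bead 0 but never applied by the integrator.
// ---------------------------------------------------------------------------

static void spring_forces_impl(const double* x, const double* y,
                               const double* z, int nb, double ks, double* fx,
                               double* fy, double* fz) {
  // nb = number of beads (N+1); bonds n -> n+1, equilibrium length 1
  for (int n = 0; n < nb; ++n) fx[n] = fy[n] = fz[n] = 0.0;
  for (int n = 0; n < nb - 1; ++n) {
    double dx = x[n + 1] - x[n], dy = y[n + 1] - y[n], dz = z[n + 1] - z[n];
    double r = std::sqrt(dx * dx + dy * dy + dz * dz);
    if (r < 1e-9) stop("degenerate bond %d-%d (coincident beads)", n, n + 1);
    double f = ks * (r - 1.0) / r;  // magnitude/r; pulls the bond to length 1
    fx[n] += f * dx;
    fy[n] += f * dy;
    fz[n] += f * dz;
    fx[n + 1] -= f * dx;
    fy[n + 1] -= f * dy;
    fz[n + 1] -= f * dz;
  }
}

static inline double wall_force_z(double z, double eps) {
  // 6*eps*[(1/z)^7 - (1/z)^4] for 0 < z <= 1, else 0 (reduced units, a = 1)
  if (z >= 1.0) return 0.0;
  double u = 1.0 / z;
  double u2 = u * u;
  double u4 = u2 * u2;
  return 6.0 * eps * (u4 * u2 * u - u4);
}

static void surface_forces_impl(const double* z, int nb, double eps,
                                double* fz) {
  for (int n = 0; n < nb; ++n) fz[n] = wall_force_z(z[n], eps);
}

static void peg_forces_impl(const double* x, const double* y, const double* z,
                            int nb, double alpha, double D, double peg,
                            int cutoff, double* fx, double* fy, double* fz) {
  for (int n = 0; n < nb; ++n) fx[n] = fy[n] = fz[n] = 0.0;
  if (alpha <= 0.0 || peg <= 0.0) return;
  double pref = alpha * peg / D;
  for (int n = 0; n < nb - 1; ++n) {
    int mmax = std::min(nb - 1, n + cutoff);
    for (int m = n + 1; m <= mmax; ++m) {
      double dx = x[m] - x[n], dy = y[m] - y[n], dz = z[m] - z[n];
      double r = std::sqrt(dx * dx + dy * dy + dz * dz);
      if (r < 1e-9) stop("coincident pair %d-%d in crowding sum", n, m);
      double f = pref * std::exp(-r / D) / r;  // attractive: pulls together
      fx[n] += f * dx;
      fy[n] += f * dy;
      fz[n] += f * dz;
      fx[m] -= f * dx;
      fy[m] -= f * dy;
      fz[m] -= f * dz;
    }
  }
}

static void split_pos(const NumericMatrix& pos, std::vector<double>& x,
                      std::vector<double>& y, std::vector<double>& z) {
  int nb = pos.nrow();
  x.resize(nb);
  y.resize(nb);
  z.resize(nb);
  for (int i = 0; i < nb; ++i) {
    x[i] = pos(i, 0);
    y[i] = pos(i, 1);
    z[i] = pos(i, 2);
  }
}

static NumericMatrix pack_forces(const std::vector<double>& fx,
                                 const std::vector<double>& fy,
                                 const std::vector<double>& fz) {
  int nb = fx.size();
  NumericMatrix out(nb, 3);
  for (int i = 0; i < nb; ++i) {
    out(i, 0) = fx[i];
    out(i, 1) = fy[i];
    out(i, 2) = fz[i];
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix spring_forces_cpp(NumericMatrix pos, double spring_k) {
  std::vector<double> x, y, z, fx(pos.nrow()), fy(pos.nrow()), fz(pos.nrow());
  split_pos(pos, x, y, z);
  spring_forces_impl(x.data(), y.data(), z.data(), pos.nrow(), spring_k,
                     fx.data(), fy.data(), fz.data());
  return pack_forces(fx, fy, fz);
}

// [[Rcpp::export]]
NumericMatrix surface_forces_cpp(NumericMatrix pos, double wall_eps) {
  int nb = pos.nrow();
  std::vector<double> fz(nb), fx(nb, 0.0), fy(nb, 0.0);
  std::vector<double> x, y, z;
  split_pos(pos, x, y, z);
  for (int i = 0; i < nb; ++i)
    if (z[i] <= 0)
      stop("bead %d has z <= 0: wall force undefined", i);
  surface_forces_impl(z.data(), nb, wall_eps, fz.data());
  return pack_forces(fx, fy, fz);
}

// [[Rcpp::export]]
NumericMatrix peg_forces_cpp(NumericMatrix pos, double alpha, double decay_d,
                             double peg_pct, int neighbor_cutoff) {
  std::vector<double> x, y, z, fx(pos.nrow()), fy(pos.nrow()), fz(pos.nrow());
  split_pos(pos, x, y, z);
  peg_forces_impl(x.data(), y.data(), z.data(), pos.nrow(), alpha, decay_d,
                  peg_pct, neighbor_cutoff, fx.data(), fy.data(), fz.data());
  return pack_forces(fx, fy, fz);
}

// [[Rcpp::export]]
double total_potential_cpp(NumericMatrix pos, double spring_k, double wall_eps,
                           double alpha, double decay_d, double peg_pct,
                           int neighbor_cutoff) {
  std::vector<double> x, y, z;
  split_pos(pos, x, y, z);
  int nb = pos.nrow();
  double u = 0.0;
  for (int n = 0; n < nb - 1; ++n) {
    double dx = x[n + 1] - x[n], dy = y[n + 1] - y[n], dz = z[n + 1] - z[n];
    double r = std::sqrt(dx * dx + dy * dy + dz * dz);
    if (r < 1e-9) stop("degenerate bond %d-%d (coincident beads)", n, n + 1);
    u += 0.5 * spring_k * (r - 1.0) * (r - 1.0);
  }
  // wall energy: antiderivative of the wall force with U(1) = 0
  for (int n = 0; n < nb; ++n) {
    double zz = z[n];
    if (zz <= 0) stop("bead %d has z <= 0: wall energy undefined", n);
    if (zz < 1.0) {
      double v = 1.0 / zz;
      double v3 = v * v * v;
      u += wall_eps * (v3 * v3 - 2.0 * v3 + 1.0);
    }
  }
  if (alpha > 0.0 && peg_pct > 0.0) {
    for (int n = 0; n < nb - 1; ++n) {
      int mmax = std::min(nb - 1, n + neighbor_cutoff);
      for (int m = n + 1; m <= mmax; ++m) {
        double dx = x[m] - x[n], dy = y[m] - y[n], dz = z[m] - z[n];
        double r = std::sqrt(dx * dx + dy * dy + dz * dz);
        if (r < 1e-9) stop("coincident pair %d-%d in crowding sum", n, m);
        u += -alpha * peg_pct * std::exp(-r / decay_d);
      }
    }
  }
  return u;
}

// ---------------------------------------------------------------------------
// Integrator
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List bd_run_cpp(NumericMatrix init, double spring_k, double wall_eps,
                double alpha, double decay_d, double peg_pct,
                int neighbor_cutoff, double peclet, double dt, double t0,
                long n_steps, int stride, double seed, bool noise_on,
                bool record_full, double z_floor, double noise_sign,
                bool gaussian_mode) {
  int nb = init.nrow();  // N + 1 beads
  std::vector<double> x, y, z;
  split_pos(init, x, y, z);
  std::vector<double> fx(nb), fy(nb), fz(nb), gx(nb), gy(nb), gz(nb);

  Rng rng((uint64_t)seed);
  double sd = noise_sign * std::sqrt(2.0 * dt);

  long n_frames = n_steps / stride + 1;
  int rec_cols = record_full ? 3 * nb : 3;
  NumericMatrix frames(n_frames, rec_cols);
  NumericVector times(n_frames);
  bool wall_warn = false;

  long frame = 0;
  auto record = [&](long step_idx) {
    times[frame] = t0 + step_idx * dt;
    if (record_full) {
      for (int i = 0; i < nb; ++i) {
        frames(frame, 3 * i) = x[i];
        frames(frame, 3 * i + 1) = y[i];
        frames(frame, 3 * i + 2) = z[i];
      }
    } else {
      frames(frame, 0) = x[nb - 1];
      frames(frame, 1) = y[nb - 1];
      frames(frame, 2) = z[nb - 1];
    }
    ++frame;
  };
  record(0);

  bool use_peg = alpha > 0.0 && peg_pct > 0.0;
  for (long i = 1; i <= n_steps; ++i) {
    if (gaussian_mode) {
      // exactly linear surrogate: rest-length-0 springs, tether fixed,
      // no wall; same noise stream layout as the real chain
      for (int n = 1; n < nb; ++n) {
        double xl = x[n - 1] - x[n], yl = y[n - 1] - y[n],
               zl = z[n - 1] - z[n];
        if (n < nb - 1) {
          xl += x[n + 1] - x[n];
          yl += y[n + 1] - y[n];
          zl += z[n + 1] - z[n];
        }
        fx[n] = spring_k * xl;
        fy[n] = spring_k * yl;
        fz[n] = spring_k * zl;
      }
      if (noise_on) {
        for (int n = 1; n < nb; ++n) {
          x[n] += (fx[n] + peclet * z[n]) * dt + sd * rnorm_zig(rng);
          y[n] += fy[n] * dt + sd * rnorm_zig(rng);
          z[n] += fz[n] * dt + sd * rnorm_zig(rng);
        }
      } else {
        for (int n = 1; n < nb; ++n) {
          x[n] += (fx[n] + peclet * z[n]) * dt;
          y[n] += fy[n] * dt;
          z[n] += fz[n] * dt;
        }
      }
      if (i % stride == 0) {
        record(i);
        if (frame % 256 == 0) Rcpp::checkUserInterrupt();
      }
      continue;
    }
    spring_forces_impl(x.data(), y.data(), z.data(), nb, spring_k, fx.data(),
                       fy.data(), fz.data());
    if (use_peg) {
      peg_forces_impl(x.data(), y.data(), z.data(), nb, alpha, decay_d,
                      peg_pct, neighbor_cutoff, gx.data(), gy.data(),
                      gz.data());
      for (int n = 1; n < nb; ++n) {
        fx[n] += gx[n];
        fy[n] += gy[n];
        fz[n] += gz[n];
      }
    }
    // bead 0 clamped: advance beads 1..N only
    if (noise_on) {
      for (int n = 1; n < nb; ++n) {
        double fwall = wall_force_z(z[n], wall_eps);
        x[n] += (fx[n] + peclet * z[n]) * dt + sd * rnorm_zig(rng);
        y[n] += fy[n] * dt + sd * rnorm_zig(rng);
        z[n] += (fz[n] + fwall) * dt + sd * rnorm_zig(rng);
      }
    } else {
      for (int n = 1; n < nb; ++n) {
        double fwall = wall_force_z(z[n], wall_eps);
        x[n] += (fx[n] + peclet * z[n]) * dt;
        y[n] += fy[n] * dt;
        z[n] += (fz[n] + fwall) * dt;
      }
    }
    for (int n = 1; n < nb; ++n) {
      if (z[n] < z_floor)
        stop("integration failure at step %ld: bead %d hit z = %.3g < z_floor "
             "(reduce dt or raise wall_eps)",
             i, n, z[n]);
      if (z[n] < 0 && !wall_warn) wall_warn = true;
    }
    if (i % stride == 0) {
      long double chk = x[nb - 1] + z[1];
      if (!std::isfinite((double)chk))
        stop("integration failure at step %ld: non-finite coordinates", i);
      record(i);
      if (frame % 256 == 0) Rcpp::checkUserInterrupt();
    }
  }

  NumericMatrix final_pos(nb, 3);
  for (int i = 0; i < nb; ++i) {
    final_pos(i, 0) = x[i];
    final_pos(i, 1) = y[i];
    final_pos(i, 2) = z[i];
  }
  return List::create(_["times"] = times, _["frames"] = frames,
                      _["final"] = final_pos, _["wall_breach"] = wall_warn);
}

// Free single bead, no forces: pure noise integration (fluctuation-
// dissipation check).  Returns replica x,y,z displacements at each of
// n_record equally spaced times.
// [[Rcpp::export]]
NumericMatrix free_bead_cpp(int n_replicas, long n_steps, double dt,
                            int n_record, double seed) {
  Rng rng((uint64_t)seed);
  double sd = std::sqrt(2.0 * dt);
  NumericMatrix out(n_replicas * n_record, 4);  // time, x, y, z
  long per = n_steps / n_record;
  for (int r = 0; r < n_replicas; ++r) {
    double x = 0, y = 0, z = 0;
    for (int k = 0; k < n_record; ++k) {
      for (long i = 0; i < per; ++i) {
        x += sd * rnorm_zig(rng);
        y += sd * rnorm_zig(rng);
        z += sd * rnorm_zig(rng);
      }
      int row = r * n_record + k;
      out(row, 0) = (k + 1) * per * dt;
      out(row, 1) = x;
      out(row, 2) = y;
      out(row, 3) = z;
    }
  }
  return out;
}
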