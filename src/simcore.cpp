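// Langevin-dynamics core for the confined Kremer-Grest chain.
// Reduced LJ units throughout (sigma = eps = tau = m = 1 unless overridden).
// Confinements are axis-aligned and centered at the origin at this level;
// the R wrappers guarantee that frame.
//
// Pair handling: Verlet neighbor list with a 0.4 sigma skin, rebuilt when
// any bead has moved more than half the skin since the last build.
// Polymer-polymer candidates come from an O(N^2) sweep at build time (N is
// a few hundred at most); wall shell beads (which can number tens of
// thousands) are looked up through a static cell grid.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

struct FF {
  double k_fene, R0, eps, sig, wall_eps, spacing, k_bend;
};

static FF ff_from_list(List ffp) {
  FF ff;
  ff.k_fene   = as<double>(ffp["k_fene"]);
  ff.R0       = as<double>(ffp["R0"]);
  ff.eps      = as<double>(ffp["eps_wca"]);
  ff.sig      = as<double>(ffp["sigma"]);
  ff.wall_eps = as<double>(ffp["wall_eps"]);
  ff.spacing  = as<double>(ffp["wall_spacing"]);
  ff.k_bend   = as<double>(ffp["k_bend"]);
  return ff;
}

// ---- fast RNG: xoshiro256++ with polar-method normals --------------------

struct Rng {
  uint64_t s[4];
  double spare;
  bool has_spare;
  explicit Rng(uint64_t seed) : has_spare(false), spare(0.0) {
    // splitmix64 seeding
    uint64_t z = seed;
    for (int i = 0; i < 4; ++i) {
      z += 0x9e3779b97f4a7c15ULL;
      uint64_t t = z;
      t = (t ^ (t >> 30)) * 0xbf58476d1ce4e5b9ULL;
      t = (t ^ (t >> 27)) * 0x94d049bb133111ebULL;
      s[i] = t ^ (t >> 31);
    }
  }
  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  inline uint64_t next() {
    uint64_t res = rotl(s[0] + s[3], 23) + s[0];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return res;
  }
  inline double unif() {  // (0, 1)
    return ((next() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
  inline double gauss() {
    if (has_spare) { has_spare = false; return spare; }
    double u, v, q;
    do {
      u = 2.0 * unif() - 1.0;
      v = 2.0 * unif() - 1.0;
      q = u * u + v * v;
    } while (q >= 1.0 || q == 0.0);
    double f = std::sqrt(-2.0 * std::log(q) / q);
    spare = v * f;
    has_spare = true;
    return u * f;
  }
};

// ---- potentials ----------------------------------------------------------

// WCA scalar force over r (f/r), so the force on i from j is
// (f/r) * (xi - xj); positive = repulsive. Valid for r2 < rc2.
static inline double wca_f_over_r(double r2, double eps, double sig2) {
  double s2 = sig2 / r2;
  double s6 = s2 * s2 * s2;
  return 24.0 * eps * (2.0 * s6 * s6 - s6) / r2;
}

static inline double wca_u(double r2, double eps, double sig2) {
  double s2 = sig2 / r2;
  double s6 = s2 * s2 * s2;
  return 4.0 * eps * (s6 * s6 - s6) + eps;
}

// Integral of U_wca(r) * r dr, for the sheet wall potential.
static inline double wca_u_rdr_integral(double r, double eps, double sig) {
  double s6 = std::pow(sig / r, 6.0);
  double s12 = s6 * s6;
  return 4.0 * eps * (-s12 * r * r / 10.0 + s6 * r * r / 4.0) +
         eps * r * r / 2.0;
}

// ---- static cell grid for shell beads ------------------------------------

struct ShellGrid {
  double cell, x0, y0, z0;
  int nx, ny, nz;
  std::vector<int> head, nxt;
  void build(const std::vector<double>& S, int n_shell, const double axes[3],
             double cellsize) {
    cell = cellsize;
    double pad = 2.0;
    x0 = -(axes[0] + pad); y0 = -(axes[1] + pad); z0 = -(axes[2] + pad);
    nx = std::max(1, (int)std::ceil(2.0 * (axes[0] + pad) / cell));
    ny = std::max(1, (int)std::ceil(2.0 * (axes[1] + pad) / cell));
    nz = std::max(1, (int)std::ceil(2.0 * (axes[2] + pad) / cell));
    head.assign((size_t)nx * ny * nz, -1);
    nxt.assign(std::max(1, n_shell), -1);
    for (int j = 0; j < n_shell; ++j) {
      int c = idx(cx(S[3 * j]), cy(S[3 * j + 1]), cz(S[3 * j + 2]));
      nxt[j] = head[c];
      head[c] = j;
    }
  }
  inline int clampi(int i, int n) const {
    return i < 0 ? 0 : (i >= n ? n - 1 : i);
  }
  inline int cx(double x) const { return clampi((int)((x - x0) / cell), nx); }
  inline int cy(double y) const { return clampi((int)((y - y0) / cell), ny); }
  inline int cz(double z) const { return clampi((int)((z - z0) / cell), nz); }
  inline int idx(int ix, int iy, int iz) const {
    return (iz * ny + iy) * nx + ix;
  }
};

// ---- Verlet neighbor list ------------------------------------------------

struct NeighborList {
  double rlist2, skin_half2;
  std::vector<int> pstart, plist;  // polymer-polymer, j > i
  std::vector<int> sstart, slist;  // polymer-shell
  std::vector<double> Xref;

  void init(int N, double cutoff, double skin) {
    rlist2 = (cutoff + skin) * (cutoff + skin);
    skin_half2 = 0.25 * skin * skin;
    pstart.assign(N + 1, 0);
    sstart.assign(N + 1, 0);
    Xref.assign(3 * N, 1e30);
  }
  void invalidate() { std::fill(Xref.begin(), Xref.end(), 1e30); }
  bool stale(const std::vector<double>& X, int N) const {
    for (int i = 0; i < N; ++i) {
      double dx = X[3 * i] - Xref[3 * i];
      double dy = X[3 * i + 1] - Xref[3 * i + 1];
      double dz = X[3 * i + 2] - Xref[3 * i + 2];
      if (dx * dx + dy * dy + dz * dz > skin_half2) return true;
    }
    return false;
  }
  void build(const std::vector<double>& X, int N,
             const std::vector<double>& S, int n_shell,
             const ShellGrid* grid) {
    plist.clear();
    slist.clear();
    for (int i = 0; i < N; ++i) {
      pstart[i] = (int)plist.size();
      for (int j = i + 1; j < N; ++j) {
        double dx = X[3 * i] - X[3 * j];
        double dy = X[3 * i + 1] - X[3 * j + 1];
        double dz = X[3 * i + 2] - X[3 * j + 2];
        if (dx * dx + dy * dy + dz * dz < rlist2) plist.push_back(j);
      }
      sstart[i] = (int)slist.size();
      if (grid && n_shell > 0) {
        int ix = grid->cx(X[3 * i]), iy = grid->cy(X[3 * i + 1]),
            iz = grid->cz(X[3 * i + 2]);
        for (int dz_ = -1; dz_ <= 1; ++dz_)
          for (int dy_ = -1; dy_ <= 1; ++dy_)
            for (int dx_ = -1; dx_ <= 1; ++dx_) {
              int jx = ix + dx_, jy = iy + dy_, jz = iz + dz_;
              if (jx < 0 || jy < 0 || jz < 0 || jx >= grid->nx ||
                  jy >= grid->ny || jz >= grid->nz) continue;
              for (int j = grid->head[grid->idx(jx, jy, jz)]; j >= 0;
                   j = grid->nxt[j]) {
                double dx = X[3 * i] - S[3 * j];
                double dy = X[3 * i + 1] - S[3 * j + 1];
                double dz = X[3 * i + 2] - S[3 * j + 2];
                if (dx * dx + dy * dy + dz * dz < rlist2)
                  slist.push_back(j);
              }
            }
      }
    }
    pstart[N] = (int)plist.size();
    sstart[N] = (int)slist.size();
    Xref = X;
  }
};

// ---- force evaluation ----------------------------------------------------

struct System {
  int N, n_shell, wall_mode;  // 0 none, 1 analytic sheet, 2 shell beads
  FF ff;
  double axes[3];
  std::vector<double> S;
  ShellGrid grid;
  NeighborList nl;
  static constexpr double SKIN = 0.4;

  void setup(const NumericMatrix& x0, const NumericVector& axes_,
             int wall_mode_, const NumericMatrix& shell_, List ffp) {
    N = x0.nrow();
    ff = ff_from_list(ffp);
    wall_mode = wall_mode_;
    axes[0] = axes[1] = axes[2] = 0.0;
    if (axes_.size() == 3) {
      axes[0] = axes_[0]; axes[1] = axes_[1]; axes[2] = axes_[2];
    }
    n_shell = (wall_mode == 2) ? shell_.nrow() : 0;
    S.assign(3 * std::max(1, n_shell), 0.0);
    for (int j = 0; j < n_shell; ++j)
      for (int k = 0; k < 3; ++k) S[3 * j + k] = shell_(j, k);
    double rc = std::pow(2.0, 1.0 / 6.0) * ff.sig;
    if (n_shell > 0) grid.build(S, n_shell, axes, rc + SKIN);
    nl.init(N, rc, SKIN);
  }

  // Returns -1 on success, else the index of a bad (overstretched) bond.
  int forces(const std::vector<double>& X, double fcap,
             std::vector<double>& F, double* epot) {
    return forces_at(X, fcap, F, epot, wall_mode, axes);
  }

  int forces_at(const std::vector<double>& X, double fcap,
                std::vector<double>& F, double* epot, int mode_now,
                const double* ax_now) {
    if (nl.stale(X, N))
      nl.build(X, N, S, n_shell, n_shell > 0 ? &grid : nullptr);
    std::fill(F.begin(), F.end(), 0.0);
    if (epot) *epot = 0.0;
    const double sig2 = ff.sig * ff.sig;
    const double rc2 = std::pow(2.0, 1.0 / 3.0) * sig2;
    const double rc = std::sqrt(rc2);
    const double R02 = ff.R0 * ff.R0;

    for (int i = 0; i < N - 1; ++i) {  // FENE bonds
      double dx = X[3 * i] - X[3 * (i + 1)];
      double dy = X[3 * i + 1] - X[3 * (i + 1) + 1];
      double dz = X[3 * i + 2] - X[3 * (i + 1) + 2];
      double r2 = dx * dx + dy * dy + dz * dz;
      if (r2 >= R02 || !std::isfinite(r2)) return i;
      double denom = 1.0 - r2 / R02;
      double f_over_r = -ff.k_fene / denom;  // attractive
      F[3 * i]     += f_over_r * dx;  F[3 * (i + 1)]     -= f_over_r * dx;
      F[3 * i + 1] += f_over_r * dy;  F[3 * (i + 1) + 1] -= f_over_r * dy;
      F[3 * i + 2] += f_over_r * dz;  F[3 * (i + 1) + 2] -= f_over_r * dz;
      if (epot) *epot += -0.5 * ff.k_fene * R02 * std::log(denom);
    }

    if (ff.k_bend > 0.0) {             // angular stiffness U = kb (1 - cos)
      for (int i = 1; i < N - 1; ++i) {
        double b1x = X[3 * i] - X[3 * (i - 1)];
        double b1y = X[3 * i + 1] - X[3 * (i - 1) + 1];
        double b1z = X[3 * i + 2] - X[3 * (i - 1) + 2];
        double b2x = X[3 * (i + 1)] - X[3 * i];
        double b2y = X[3 * (i + 1) + 1] - X[3 * i + 1];
        double b2z = X[3 * (i + 1) + 2] - X[3 * i + 2];
        double n1 = std::sqrt(b1x * b1x + b1y * b1y + b1z * b1z);
        double n2 = std::sqrt(b2x * b2x + b2y * b2y + b2z * b2z);
        double e1x = b1x / n1, e1y = b1y / n1, e1z = b1z / n1;
        double e2x = b2x / n2, e2y = b2y / n2, e2z = b2z / n2;
        double ct = e1x * e2x + e1y * e2y + e1z * e2z;
        // d cos / d r_(i-1) = -(e2 - ct e1)/n1 ; d cos / d r_(i+1) = (e1 - ct e2)/n2
        double gax = -(e2x - ct * e1x) / n1, gay = -(e2y - ct * e1y) / n1,
               gaz = -(e2z - ct * e1z) / n1;
        double gcx = (e1x - ct * e2x) / n2, gcy = (e1y - ct * e2y) / n2,
               gcz = (e1z - ct * e2z) / n2;
        F[3 * (i - 1)]     += ff.k_bend * gax;
        F[3 * (i - 1) + 1] += ff.k_bend * gay;
        F[3 * (i - 1) + 2] += ff.k_bend * gaz;
        F[3 * (i + 1)]     += ff.k_bend * gcx;
        F[3 * (i + 1) + 1] += ff.k_bend * gcy;
        F[3 * (i + 1) + 2] += ff.k_bend * gcz;
        F[3 * i]     -= ff.k_bend * (gax + gcx);
        F[3 * i + 1] -= ff.k_bend * (gay + gcy);
        F[3 * i + 2] -= ff.k_bend * (gaz + gcz);
        if (epot) *epot += ff.k_bend * (1.0 - ct);
      }
    }

    for (int i = 0; i < N; ++i) {      // WCA pairs (incl. bonded neighbours)
      for (int m = nl.pstart[i]; m < nl.pstart[i + 1]; ++m) {
        int j = nl.plist[m];
        double dx = X[3 * i] - X[3 * j];
        double dy = X[3 * i + 1] - X[3 * j + 1];
        double dz = X[3 * i + 2] - X[3 * j + 2];
        double r2 = dx * dx + dy * dy + dz * dz;
        if (r2 >= rc2) continue;
        double f_over_r = wca_f_over_r(r2, ff.eps, sig2);
        if (fcap > 0.0) {
          double r = std::sqrt(r2);
          if (f_over_r * r > fcap) f_over_r = fcap / r;
        }
        F[3 * i]     += f_over_r * dx;  F[3 * j]     -= f_over_r * dx;
        F[3 * i + 1] += f_over_r * dy;  F[3 * j + 1] -= f_over_r * dy;
        F[3 * i + 2] += f_over_r * dz;  F[3 * j + 2] -= f_over_r * dz;
        if (epot) *epot += wca_u(r2, ff.eps, sig2);
      }
    }

    if (mode_now == 1) {               // analytic sheet wall
      const double n_area = 1.0 / (ff.spacing * ff.spacing);
      for (int i = 0; i < N; ++i) {
        double qx = X[3 * i] / ax_now[0], qy = X[3 * i + 1] / ax_now[1],
               qz = X[3 * i + 2] / ax_now[2];
        double f = qx * qx + qy * qy + qz * qz;
        double s = std::sqrt(f);
        if (s < 1e-12) continue;
        double gx = qx / (ax_now[0] * s), gy = qy / (ax_now[1] * s),
               gz = qz / (ax_now[2] * s);
        double gn = std::sqrt(gx * gx + gy * gy + gz * gz);
        double d = (1.0 - s) / gn;
        // clamp the depth: bounded inward force for beads at or beyond the
        // surface (keeps the integrator stable while compressing)
        if (d < 0.7 * ff.sig) d = 0.7 * ff.sig;
        if (d >= rc) continue;
        double fmag = 2.0 * M_PI * n_area * d *
                      wca_u(d * d, ff.wall_eps, sig2);
        if (fcap > 0.0 && fmag > fcap) fmag = fcap;
        F[3 * i]     -= fmag * gx / gn;
        F[3 * i + 1] -= fmag * gy / gn;
        F[3 * i + 2] -= fmag * gz / gn;
        if (epot)
          *epot += 2.0 * M_PI * n_area *
                   (wca_u_rdr_integral(rc, ff.wall_eps, ff.sig) -
                    wca_u_rdr_integral(d, ff.wall_eps, ff.sig));
      }
    } else if (mode_now == 2) {        // shell-bead wall
      for (int i = 0; i < N; ++i) {
        for (int m = nl.sstart[i]; m < nl.sstart[i + 1]; ++m) {
          int j = nl.slist[m];
          double dx = X[3 * i] - S[3 * j];
          double dy = X[3 * i + 1] - S[3 * j + 1];
          double dz = X[3 * i + 2] - S[3 * j + 2];
          double r2 = dx * dx + dy * dy + dz * dz;
          if (r2 >= rc2 || r2 <= 0.0) continue;
          double f_over_r = wca_f_over_r(r2, ff.wall_eps, sig2);
          if (fcap > 0.0) {
            double r = std::sqrt(r2);
            if (f_over_r * r > fcap) f_over_r = fcap / r;
          }
          F[3 * i]     += f_over_r * dx;
          F[3 * i + 1] += f_over_r * dy;
          F[3 * i + 2] += f_over_r * dz;
          if (epot) *epot += wca_u(r2, ff.wall_eps, sig2);
        }
      }
    }
    return -1;
  }
};

// ---- Langevin BAOAB integrator ------------------------------------------

// [[Rcpp::export]]
List md_run_cpp(NumericMatrix x0, NumericVector axes_, int wall_mode,
                NumericMatrix shell_, List ffp, double dt, double gamma,
                double kT, int n_equil, int n_prod, int sample_every,
                int seed, bool record_energy,
                NumericVector axes_start, int n_compress) {
  System sys;
  sys.setup(x0, axes_, wall_mode, shell_, ffp);
  const int N = sys.N;
  // optional compression phase: the confinement starts at axes_start and
  // shrinks linearly to the target over n_compress steps (analytic wall)
  const bool compressing = (axes_start.size() == 3) && n_compress > 0;
  double ax0[3] = {0, 0, 0};
  if (compressing) { ax0[0] = axes_start[0]; ax0[1] = axes_start[1]; ax0[2] = axes_start[2]; }

  std::vector<double> X(3 * N), V(3 * N), F(3 * N);
  for (int i = 0; i < N; ++i)
    for (int k = 0; k < 3; ++k) X[3 * i + k] = x0(i, k);

  Rng rng((uint64_t)(uint32_t)seed);
  double sd_v = std::sqrt(kT);
  for (int i = 0; i < 3 * N; ++i) V[i] = sd_v * rng.gauss();

  const double c1 = std::exp(-gamma * dt);
  const double c2 = std::sqrt(std::max(0.0, (1.0 - c1 * c1) * kT));

  double epot = 0.0;
  int bad = compressing
      ? sys.forces_at(X, 0.0, F, nullptr, 1, ax0)
      : sys.forces(X, 0.0, F, record_energy ? &epot : nullptr);
  if (bad >= 0)
    stop("bond %d overstretched in the initial configuration", bad + 1);

  const int n_frames = (sample_every > 0) ? n_prod / sample_every : 0;
  NumericVector frames((R_xlen_t)3 * N * std::max(1, n_frames));
  IntegerVector step_index(std::max(1, n_frames));
  std::vector<double> energies;
  double ekin_sum = 0.0;
  long ekin_n = 0;
  int frame = 0;

  const long n_pre = compressing ? (long)n_compress : 0L;
  const long n_skip = n_pre + n_equil;   // steps before production
  const long total = n_skip + n_prod;
  double ax_now[3];
  for (long step = 1; step <= total; ++step) {
    int mode_now = sys.wall_mode;
    const double* ax_p = sys.axes;
    if (compressing && step <= n_pre) {
      double frac = (double)step / n_pre;
      for (int k = 0; k < 3; ++k)
        ax_now[k] = ax0[k] + (sys.axes[k] - ax0[k]) * frac;
      ax_p = ax_now;
      mode_now = 1;
    } else if (compressing && step == n_pre + 1) {
      sys.nl.invalidate();   // shell neighbours become relevant now
    }
    for (int i = 0; i < 3 * N; ++i) V[i] += 0.5 * dt * F[i];   // B
    for (int i = 0; i < 3 * N; ++i) X[i] += 0.5 * dt * V[i];   // A
    if (gamma > 0.0)                                           // O
      for (int i = 0; i < 3 * N; ++i) V[i] = c1 * V[i] + c2 * rng.gauss();
    if (step > n_skip) {
      // kinetic energy sampled at the O midpoint (exact OU marginal)
      double ek = 0.0;
      for (int i = 0; i < 3 * N; ++i) ek += V[i] * V[i];
      ekin_sum += 0.5 * ek;
      ++ekin_n;
    }
    for (int i = 0; i < 3 * N; ++i) X[i] += 0.5 * dt * V[i];   // A
    bool want_e = record_energy && step > n_skip && sample_every > 0 &&
                  ((step - n_skip) % sample_every == 0);
    bad = sys.forces_at(X, 0.0, F, want_e ? &epot : nullptr, mode_now, ax_p);
    if (bad >= 0)
      stop("bond %d overstretched (or non-finite) at step %ld", bad + 1, step);
    for (int i = 0; i < 3 * N; ++i) V[i] += 0.5 * dt * F[i];   // B

    if (step > n_skip && sample_every > 0) {
      long ps = step - n_skip;
      if (ps % sample_every == 0 && frame < n_frames) {
        for (int i = 0; i < N; ++i)
          for (int k = 0; k < 3; ++k)
            frames[(R_xlen_t)frame * 3 * N + (R_xlen_t)k * N + i] =
                X[3 * i + k];
        step_index[frame] = (int)step;
        if (record_energy) {
          double ek = 0.0;
          for (int i = 0; i < 3 * N; ++i) ek += V[i] * V[i];
          energies.push_back(epot + 0.5 * ek);
        }
        ++frame;
      }
    }
  }

  frames.attr("dim") = IntegerVector::create(N, 3, std::max(1, n_frames));
  return List::create(
      _["frames"] = frames, _["step_index"] = step_index,
      _["n_frames"] = n_frames,
      _["ekin_per_bead"] = (ekin_n > 0) ? ekin_sum / (ekin_n * N) : NA_REAL,
      _["energy"] = wrap(energies));
}

// Overdamped push-off with a ramped force cap: resolves the overlaps of a
// fresh random-walk initialization without FENE blow-up.
// [[Rcpp::export]]
NumericMatrix pushoff_cpp(NumericMatrix x0, NumericVector axes_, int wall_mode,
                          NumericMatrix shell_, List ffp, int n_steps,
                          double fcap_start, double fcap_end,
                          double max_disp) {
  System sys;
  sys.setup(x0, axes_, wall_mode, shell_, ffp);
  const int N = sys.N;
  std::vector<double> X(3 * N), F(3 * N);
  for (int i = 0; i < N; ++i)
    for (int k = 0; k < 3; ++k) X[3 * i + k] = x0(i, k);

  const double h = 5e-4;  // overdamped step (displacement per unit force)
  for (int s = 0; s < n_steps; ++s) {
    double frac = (n_steps > 1) ? (double)s / (n_steps - 1) : 1.0;
    double fcap = fcap_start * std::pow(fcap_end / fcap_start, frac);
    int bad = sys.forces(X, fcap, F, nullptr);
    if (bad >= 0) stop("bond %d overstretched during push-off", bad + 1);
    for (int i = 0; i < N; ++i) {
      double dx = h * F[3 * i], dy = h * F[3 * i + 1], dz = h * F[3 * i + 2];
      double d = std::sqrt(dx * dx + dy * dy + dz * dz);
      if (d > max_disp) {
        dx *= max_disp / d; dy *= max_disp / d; dz *= max_disp / d;
      }
      X[3 * i] += dx; X[3 * i + 1] += dy; X[3 * i + 2] += dz;
    }
  }
  NumericMatrix out(N, 3);
  for (int i = 0; i < N; ++i)
    for (int k = 0; k < 3; ++k) out(i, k) = X[3 * i + k];
  return out;
}

// Per-contour-separation pair statistics over a stack of frames:
// counts of pairs with |i-j| = k closer than cutoff, and the sum of squared
// distances, for k = 1 .. N-1.
// [[Rcpp::export]]
List pair_profile_cpp(NumericVector frames, double cutoff) {
  IntegerVector dim = frames.attr("dim");
  const int N = dim[0], nf = dim[2];
  const double c2 = cutoff * cutoff;
  std::vector<double> r2sum(N - 1, 0.0);
  std::vector<double> ncontact(N - 1, 0.0);
  for (int f = 0; f < nf; ++f) {
    const double* fx = &frames[(R_xlen_t)f * 3 * N];
    const double* fy = fx + N;
    const double* fz = fy + N;
    for (int i = 0; i < N - 1; ++i)
      for (int j = i + 1; j < N; ++j) {
        double dx = fx[i] - fx[j], dy = fy[i] - fy[j], dz = fz[i] - fz[j];
        double r2 = dx * dx + dy * dy + dz * dz;
        int k = j - i;
        r2sum[k - 1] += r2;
        if (r2 < c2) ncontact[k - 1] += 1.0;
      }
  }
  return List::create(_["r2_sum"] = wrap(r2sum),
                      _["contacts"] = wrap(ncontact),
                      _["n_frames"] = nf);
}
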