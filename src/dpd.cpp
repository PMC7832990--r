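// Groot-Warren dissipative particle dynamics kernels.
//
// Reduced units throughout: rc = 1 (length), bead mass m = 1, kBT = 1.
// Conservative force a_ij (1 - r) rhat for r < 1; dissipative
// -gamma w(r)^2 (rhat . v_ij) rhat; random sigma w(r) theta rhat / sqrt(dt)
// with w(r) = 1 - r and theta symmetric per pair, unit variance.
// Bonds are zero-rest-length harmonic springs F = -C r.

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <vector>

using namespace Rcpp;

namespace {

// xorshift-free deterministic generator: 64-bit splitmix for seeding a
// small-state PCG-like stream. Implementation-defined std distributions are
// avoided so trajectories are bit-identical for a given seed everywhere.
struct Rng {
  uint64_t s;
  explicit Rng(uint64_t seed) : s(seed + 0x9E3779B97F4A7C15ULL) {
    next();
    next();
  }
  uint64_t next() {
    uint64_t z = (s += 0x9E3779B97F4A7C15ULL);
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }
  // uniform in (0, 1)
  double unif() {
    return (next() >> 11) * (1.0 / 9007199254740992.0) +
           (0.5 / 9007199254740992.0);
  }
  // zero-mean, unit-variance uniform noise (standard DPD choice)
  double theta() { return 1.7320508075688772 * (2.0 * unif() - 1.0); }
};

struct Sys {
  int n;
  std::vector<double> x, y, z, vx, vy, vz;
  std::vector<int> sp;
  double Lx, Ly, Lz;
};

inline double wrap(double u, double L) {
  u -= L * std::floor(u / L);
  if (u >= L) u -= L;  // guard the u/L rounding edge
  return u;
}

inline double minimg(double d, double L) {
  if (d > 0.5 * L) d -= L;
  else if (d < -0.5 * L) d += L;
  return d;
}

struct PairParams {
  const double* a;  // ns x ns, column-major
  int ns;
  double gamma, sigma, inv_sqrt_dt;
  bool random;
};

struct ForceAcc {
  std::vector<double> fx, fy, fz;
  double epot;
  explicit ForceAcc(int n) : fx(n, 0.0), fy(n, 0.0), fz(n, 0.0), epot(0.0) {}
};

inline void pair_interact(const Sys& s, int i, int j, const PairParams& pp,
                          Rng* rng, ForceAcc& acc) {
  double dx = minimg(s.x[i] - s.x[j], s.Lx);
  double dy = minimg(s.y[i] - s.y[j], s.Ly);
  double dz = minimg(s.z[i] - s.z[j], s.Lz);
  double r2 = dx * dx + dy * dy + dz * dz;
  if (r2 >= 1.0 || r2 < 1e-24) return;
  double r = std::sqrt(r2);
  double w = 1.0 - r;
  double ex = dx / r, ey = dy / r, ez = dz / r;
  double aij = pp.a[s.sp[i] + pp.ns * s.sp[j]];
  double fmag = aij * w;
  acc.epot += 0.5 * aij * w * w;
  if (pp.gamma > 0.0) {
    double dvx = s.vx[i] - s.vx[j];
    double dvy = s.vy[i] - s.vy[j];
    double dvz = s.vz[i] - s.vz[j];
    double edv = ex * dvx + ey * dvy + ez * dvz;
    fmag -= pp.gamma * w * w * edv;
  }
  if (pp.random && rng != nullptr) {
    fmag += pp.sigma * w * rng->theta() * pp.inv_sqrt_dt;
  }
  acc.fx[i] += fmag * ex;
  acc.fy[i] += fmag * ey;
  acc.fz[i] += fmag * ez;
  acc.fx[j] -= fmag * ex;
  acc.fy[j] -= fmag * ey;
  acc.fz[j] -= fmag * ez;
}

void bond_interact(const Sys& s, const IntegerMatrix& bonds, double spring_c,
                   ForceAcc& acc) {
  int nb = bonds.nrow();
  for (int b = 0; b < nb; ++b) {
    int i = bonds(b, 0), j = bonds(b, 1);
    double dx = minimg(s.x[i] - s.x[j], s.Lx);
    double dy = minimg(s.y[i] - s.y[j], s.Ly);
    double dz = minimg(s.z[i] - s.z[j], s.Lz);
    acc.fx[i] -= spring_c * dx;
    acc.fy[i] -= spring_c * dy;
    acc.fz[i] -= spring_c * dz;
    acc.fx[j] += spring_c * dx;
    acc.fy[j] += spring_c * dy;
    acc.fz[j] += spring_c * dz;
    acc.epot += 0.5 * spring_c * (dx * dx + dy * dy + dz * dz);
  }
}

void forces_brute(const Sys& s, const PairParams& pp, Rng* rng,
                  ForceAcc& acc) {
  for (int i = 0; i < s.n; ++i)
    for (int j = i + 1; j < s.n; ++j) pair_interact(s, i, j, pp, rng, acc);
}

// cell list with half stencil; falls back to brute force when the box is
// too small for >= 3 cells per axis
void forces_cell(const Sys& s, const PairParams& pp, Rng* rng,
                 ForceAcc& acc) {
  int ncx = (int)std::floor(s.Lx), ncy = (int)std::floor(s.Ly),
      ncz = (int)std::floor(s.Lz);
  if (ncx < 3 || ncy < 3 || ncz < 3) {
    forces_brute(s, pp, rng, acc);
    return;
  }
  int ncell = ncx * ncy * ncz;
  std::vector<int> head(ncell, -1), nxt(s.n, -1);
  auto cidx = [&](double px, double py, double pz) {
    int ix = (int)(px / s.Lx * ncx);
    int iy = (int)(py / s.Ly * ncy);
    int iz = (int)(pz / s.Lz * ncz);
    if (ix >= ncx) ix = ncx - 1;
    if (iy >= ncy) iy = ncy - 1;
    if (iz >= ncz) iz = ncz - 1;
    return ix + ncx * (iy + ncy * iz);
  };
  for (int i = 0; i < s.n; ++i) {
    int c = cidx(s.x[i], s.y[i], s.z[i]);
    nxt[i] = head[c];
    head[c] = i;
  }
  // 13 half-stencil neighbour offsets + same cell
  static const int off[13][3] = {
      {1, 0, 0},  {-1, 1, 0}, {0, 1, 0},  {1, 1, 0},  {-1, -1, 1},
      {0, -1, 1}, {1, -1, 1}, {-1, 0, 1}, {0, 0, 1},  {1, 0, 1},
      {-1, 1, 1}, {0, 1, 1},  {1, 1, 1}};
  for (int iz = 0; iz < ncz; ++iz)
    for (int iy = 0; iy < ncy; ++iy)
      for (int ix = 0; ix < ncx; ++ix) {
        int c = ix + ncx * (iy + ncy * iz);
        for (int i = head[c]; i != -1; i = nxt[i])
          for (int j = nxt[i]; j != -1; j = nxt[j])
            pair_interact(s, i, j, pp, rng, acc);
        for (int k = 0; k < 13; ++k) {
          int jx = (ix + off[k][0] + ncx) % ncx;
          int jy = (iy + off[k][1] + ncy) % ncy;
          int jz = (iz + off[k][2] + ncz) % ncz;
          int c2 = jx + ncx * (jy + ncy * jz);
          for (int i = head[c]; i != -1; i = nxt[i])
            for (int j = head[c2]; j != -1; j = nxt[j])
              pair_interact(s, i, j, pp, rng, acc);
        }
      }
}

Sys make_sys(const NumericMatrix& pos, const NumericMatrix& vel,
             const IntegerVector& species, const NumericVector& box) {
  Sys s;
  s.n = pos.nrow();
  s.Lx = box[0];
  s.Ly = box[1];
  s.Lz = box[2];
  s.x.resize(s.n);
  s.y.resize(s.n);
  s.z.resize(s.n);
  s.vx.resize(s.n);
  s.vy.resize(s.n);
  s.vz.resize(s.n);
  s.sp.resize(s.n);
  for (int i = 0; i < s.n; ++i) {
    s.x[i] = wrap(pos(i, 0), s.Lx);
    s.y[i] = wrap(pos(i, 1), s.Ly);
    s.z[i] = wrap(pos(i, 2), s.Lz);
    s.vx[i] = vel(i, 0);
    s.vy[i] = vel(i, 1);
    s.vz[i] = vel(i, 2);
    s.sp[i] = species[i];
  }
  return s;
}

}  // namespace

// [[Rcpp::export]]
List dpd_forces_cpp(NumericMatrix pos, NumericMatrix vel,
                    IntegerVector species, NumericMatrix a,
                    IntegerMatrix bonds, NumericVector box, double gamma,
                    double sigma, double dt, double spring_c, bool random,
                    double seed, bool brute) {
  Sys s = make_sys(pos, vel, species, box);
  for (int i = 0; i < s.n; ++i) {
    if (!std::isfinite(s.x[i]) || !std::isfinite(s.y[i]) ||
        !std::isfinite(s.z[i])) {
      stop("non-finite positions in force evaluation");
    }
  }
  PairParams pp{REAL(a), a.nrow(), gamma, sigma,
                dt > 0 ? 1.0 / std::sqrt(dt) : 0.0, random};
  Rng rng((uint64_t)seed);
  ForceAcc acc(s.n);
  if (brute)
    forces_brute(s, pp, random ? &rng : nullptr, acc);
  else
    forces_cell(s, pp, random ? &rng : nullptr, acc);
  bond_interact(s, bonds, spring_c, acc);
  NumericMatrix f(s.n, 3);
  for (int i = 0; i < s.n; ++i) {
    f(i, 0) = acc.fx[i];
    f(i, 1) = acc.fy[i];
    f(i, 2) = acc.fz[i];
  }
  return List::create(_["forces"] = f, _["epot"] = acc.epot);
}

// [[Rcpp::export]]
List dpd_run_cpp(NumericMatrix pos, NumericMatrix vel, IntegerVector species,
                 NumericMatrix a, IntegerMatrix bonds, NumericVector box,
                 double dt, double gamma, double sigma, double lambda,
                 double spring_c, int n_steps, int snapshot_every,
                 double seed, bool keep_snapshots) {
  Sys s = make_sys(pos, vel, species, box);
  PairParams pp{REAL(a), a.nrow(), gamma, sigma,
                dt > 0 ? 1.0 / std::sqrt(dt) : 0.0, sigma > 0.0};
  Rng rng((uint64_t)seed);
  Rng* rp = pp.random ? &rng : nullptr;
  int n = s.n;

  // guard against non-finite coordinates before any neighbour search:
  // a blown-up configuration would otherwise index cells out of range
  auto check_finite = [&](int step) {
    for (int i = 0; i < n; ++i) {
      if (!std::isfinite(s.x[i]) || !std::isfinite(s.y[i]) ||
          !std::isfinite(s.z[i])) {
        stop("numerical blow-up (non-finite positions) at step %d", step);
      }
    }
  };
  check_finite(1);

  ForceAcc acc(n);
  forces_cell(s, pp, rp, acc);
  bond_interact(s, bonds, spring_c, acc);

  int n_snap = n_steps / snapshot_every;
  NumericVector snap_step(n_snap), snap_temp(n_snap), snap_epot(n_snap),
      snap_pmax(n_snap);
  List snaps(keep_snapshots ? n_snap : 0);
  int isnap = 0;

  std::vector<double> vtx(n), vty(n), vtz(n);
  for (int step = 1; step <= n_steps; ++step) {
    for (int i = 0; i < n; ++i) {
      // modified velocity-Verlet: predicted velocity feeds the
      // dissipative force
      vtx[i] = s.vx[i] + lambda * dt * acc.fx[i];
      vty[i] = s.vy[i] + lambda * dt * acc.fy[i];
      vtz[i] = s.vz[i] + lambda * dt * acc.fz[i];
      s.x[i] = wrap(s.x[i] + dt * s.vx[i] + 0.5 * dt * dt * acc.fx[i], s.Lx);
      s.y[i] = wrap(s.y[i] + dt * s.vy[i] + 0.5 * dt * dt * acc.fy[i], s.Ly);
      s.z[i] = wrap(s.z[i] + dt * s.vz[i] + 0.5 * dt * dt * acc.fz[i], s.Lz);
    }
    check_finite(step);
    std::vector<double> ovx = s.vx, ovy = s.vy, ovz = s.vz;
    s.vx = vtx;
    s.vy = vty;
    s.vz = vtz;
    ForceAcc acc2(n);
    forces_cell(s, pp, rp, acc2);
    bond_interact(s, bonds, spring_c, acc2);
    for (int i = 0; i < n; ++i) {
      s.vx[i] = ovx[i] + 0.5 * dt * (acc.fx[i] + acc2.fx[i]);
      s.vy[i] = ovy[i] + 0.5 * dt * (acc.fy[i] + acc2.fy[i]);
      s.vz[i] = ovz[i] + 0.5 * dt * (acc.fz[i] + acc2.fz[i]);
    }
    acc = acc2;

    if (step % snapshot_every == 0 && isnap < n_snap) {
      double ke = 0.0, px = 0.0, py = 0.0, pz = 0.0;
      bool bad = false;
      for (int i = 0; i < n; ++i) {
        ke += s.vx[i] * s.vx[i] + s.vy[i] * s.vy[i] + s.vz[i] * s.vz[i];
        px += s.vx[i];
        py += s.vy[i];
        pz += s.vz[i];
        if (!std::isfinite(s.x[i]) || !std::isfinite(s.vx[i])) bad = true;
      }
      if (bad)
        stop("numerical blow-up (non-finite positions/velocities) at step %d",
             step);
      snap_step[isnap] = step;
      snap_temp[isnap] = n > 1 ? ke / (3.0 * n - 3.0) : 0.0;
      snap_epot[isnap] = acc.epot;
      snap_pmax[isnap] =
          std::max(std::abs(px), std::max(std::abs(py), std::abs(pz)));
      if (keep_snapshots) {
        NumericMatrix sp(n, 3);
        for (int i = 0; i < n; ++i) {
          sp(i, 0) = s.x[i];
          sp(i, 1) = s.y[i];
          sp(i, 2) = s.z[i];
        }
        snaps[isnap] = sp;
      }
      ++isnap;
    }
  }

  NumericMatrix opos(n, 3), ovel(n, 3);
  for (int i = 0; i < n; ++i) {
    opos(i, 0) = s.x[i];
    opos(i, 1) = s.y[i];
    opos(i, 2) = s.z[i];
    ovel(i, 0) = s.vx[i];
    ovel(i, 1) = s.vy[i];
    ovel(i, 2) = s.vz[i];
  }
  return List::create(
      _["positions"] = opos, _["velocities"] = ovel,
      _["log"] = DataFrame::create(_["step"] = snap_step,
                                   _["temperature"] = snap_temp,
                                   _["epot"] = snap_epot,
                                   _["net_momentum"] = snap_pmax),
      _["snapshots"] = snaps);
}
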