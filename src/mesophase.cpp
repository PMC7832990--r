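// Density deposition and iso-surface extraction for mesophase analysis.

#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

// Cloud-in-cell (trilinear) deposition onto a periodic grid of voxel
// centres; each bead contributes total weight 1, so the deposited counts
// conserve mass exactly.
// [[Rcpp::export]]
NumericVector deposit_cic_cpp(NumericMatrix pos, IntegerVector nvox,
                              NumericVector box) {
  int nx = nvox[0], ny = nvox[1], nz = nvox[2];
  double hx = box[0] / nx, hy = box[1] / ny, hz = box[2] / nz;
  NumericVector grid(nx * ny * nz);
  int n = pos.nrow();
  for (int p = 0; p < n; ++p) {
    double sx = pos(p, 0) / hx - 0.5, sy = pos(p, 1) / hy - 0.5,
           sz = pos(p, 2) / hz - 0.5;
    int ix = (int)std::floor(sx), iy = (int)std::floor(sy),
        iz = (int)std::floor(sz);
    double fx = sx - ix, fy = sy - iy, fz = sz - iz;
    for (int dx = 0; dx < 2; ++dx)
      for (int dy = 0; dy < 2; ++dy)
        for (int dz = 0; dz < 2; ++dz) {
          int gx = ((ix + dx) % nx + nx) % nx;
          int gy = ((iy + dy) % ny + ny) % ny;
          int gz = ((iz + dz) % nz + nz) % nz;
          double w = (dx ? fx : 1.0 - fx) * (dy ? fy : 1.0 - fy) *
                     (dz ? fz : 1.0 - fz);
          grid[gx + nx * (gy + ny * (size_t)gz)] += w;
        }
  }
  return grid;
}

namespace {

struct MeshAcc {
  std::vector<double> vx, vy, vz;
  std::vector<int> f;
  void tri(const double* p1, const double* p2, const double* p3) {
    int base = (int)vx.size();
    vx.push_back(p1[0]); vy.push_back(p1[1]); vz.push_back(p1[2]);
    vx.push_back(p2[0]); vy.push_back(p2[1]); vz.push_back(p2[2]);
    vx.push_back(p3[0]); vy.push_back(p3[1]); vz.push_back(p3[2]);
    f.push_back(base + 1);
    f.push_back(base + 2);
    f.push_back(base + 3);
  }
};

inline void lerp(const double* pa, double fa, const double* pb, double fb,
                 double level, double* out) {
  double t = (level - fa) / (fb - fa);
  for (int d = 0; d < 3; ++d) out[d] = pa[d] + t * (pb[d] - pa[d]);
}

// marching tetrahedra on one tet
void do_tet(const double p[4][3], const double f[4], double level,
            MeshAcc& acc) {
  int above[4], na = 0, nb = 0, below[4];
  for (int i = 0; i < 4; ++i) {
    if (f[i] > level) above[na++] = i;
    else below[nb++] = i;
  }
  if (na == 0 || na == 4) return;
  double e[4][3];
  if (na == 1 || na == 3) {
    int apex = (na == 1) ? above[0] : below[0];
    const int* others = (na == 1) ? below : above;
    for (int k = 0; k < 3; ++k)
      lerp(p[apex], f[apex], p[others[k]], f[others[k]], level, e[k]);
    acc.tri(e[0], e[1], e[2]);
  } else {  // 2 above, 2 below -> quad
    lerp(p[above[0]], f[above[0]], p[below[0]], f[below[0]], level, e[0]);
    lerp(p[above[0]], f[above[0]], p[below[1]], f[below[1]], level, e[1]);
    lerp(p[above[1]], f[above[1]], p[below[1]], f[below[1]], level, e[2]);
    lerp(p[above[1]], f[above[1]], p[below[0]], f[below[0]], level, e[3]);
    acc.tri(e[0], e[1], e[2]);
    acc.tri(e[0], e[2], e[3]);
  }
}

}  // namespace

// Marching-tetrahedra iso-surface of a scalar field sampled at voxel
// centres; open (non-periodic) boundaries. Field is a flat nx*ny*nz array
// in x-fastest order; vertex coordinates are in box units.
// [[Rcpp::export]]
List marching_tetrahedra_cpp(NumericVector field, IntegerVector nvox,
                             NumericVector box, double level) {
  int nx = nvox[0], ny = nvox[1], nz = nvox[2];
  double hx = box[0] / nx, hy = box[1] / ny, hz = box[2] / nz;
  auto F = [&](int i, int j, int k) {
    return field[i + nx * (j + ny * (size_t)k)];
  };
  // 6-tet decomposition of a cube around the 0-6 diagonal
  static const int tets[6][4] = {{0, 5, 1, 6}, {0, 1, 2, 6}, {0, 2, 3, 6},
                                 {0, 3, 7, 6}, {0, 7, 4, 6}, {0, 4, 5, 6}};
  static const int corner[8][3] = {{0, 0, 0}, {1, 0, 0}, {1, 1, 0},
                                   {0, 1, 0}, {0, 0, 1}, {1, 0, 1},
                                   {1, 1, 1}, {0, 1, 1}};
  MeshAcc acc;
  for (int k = 0; k + 1 < nz; ++k)
    for (int j = 0; j + 1 < ny; ++j)
      for (int i = 0; i + 1 < nx; ++i) {
        double cp[8][3], cf[8];
        for (int c = 0; c < 8; ++c) {
          int ci = i + corner[c][0], cj = j + corner[c][1],
              ck = k + corner[c][2];
          cp[c][0] = (ci + 0.5) * hx;
          cp[c][1] = (cj + 0.5) * hy;
          cp[c][2] = (ck + 0.5) * hz;
          cf[c] = F(ci, cj, ck);
        }
        for (int t = 0; t < 6; ++t) {
          double tp[4][3], tf[4];
          for (int v = 0; v < 4; ++v) {
            int c = tets[t][v];
            tp[v][0] = cp[c][0];
            tp[v][1] = cp[c][1];
            tp[v][2] = cp[c][2];
            tf[v] = cf[c];
          }
          do_tet(tp, tf, level, acc);
        }
      }
  int nv = (int)acc.vx.size();
  NumericMatrix verts(nv, 3);
  for (int i = 0; i < nv; ++i) {
    verts(i, 0) = acc.vx[i];
    verts(i, 1) = acc.vy[i];
    verts(i, 2) = acc.vz[i];
  }
  int nf = (int)acc.f.size() / 3;
  IntegerMatrix faces(nf, 3);
  for (int i = 0; i < nf; ++i) {
    faces(i, 0) = acc.f[3 * i];
    faces(i, 1) = acc.f[3 * i + 1];
    faces(i, 2) = acc.f[3 * i + 2];
  }
  return List::create(_["vertices"] = verts, _["faces"] = faces);
}
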