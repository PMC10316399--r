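#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Minimum-image displacement for an orthorhombic box; box[d] <= 0 means
// the dimension is not periodic.
static inline double mi3(double d, double L) {
  if (L > 0) d -= L * std::round(d / L);
  return d;
}

// 3-D linked-cell grid (orthorhombic periodic box).
struct CellGrid3 {
  int nx, ny, nz;
  double cx, cy, cz;
  NumericVector box;
  std::vector<int> head, nxt;
  CellGrid3(NumericVector box_, double range, int npts, int maxCells = 48)
      : box(box_) {
    auto dim = [&](double L) {
      int n = (L > 0) ? (int)std::floor(L / std::max(range, 1e-9)) : 1;
      if (n < 1) n = 1;
      if (n > maxCells) n = maxCells;
      return n;
    };
    nx = dim(box[0]); ny = dim(box[1]); nz = dim(box[2]);
    cx = (box[0] > 0) ? box[0] / nx : 1e9;
    cy = (box[1] > 0) ? box[1] / ny : 1e9;
    cz = (box[2] > 0) ? box[2] / nz : 1e9;
    head.assign((size_t)nx * ny * nz, -1);
    nxt.assign(npts, -1);
  }
  inline int idx(double x, double y, double z) const {
    auto c = [](double v, double cell, int n) {
      int i = (int)std::floor(v / cell);
      i %= n; if (i < 0) i += n;
      return i;
    };
    return (c(z, cz, nz) * ny + c(y, cy, ny)) * nx + c(x, cx, nx);
  }
  inline void insert(int i, double x, double y, double z) {
    int c = idx(x, y, z);
    nxt[i] = head[c]; head[c] = i;
  }
  template <class F>
  void forNeighbors(double x, double y, double z, F f) const {
    // 3x3x3 neighbourhood; duplicates possible when a dimension has < 3
    // cells, so visited cells are de-duplicated.
    int bx = (int)std::floor(x / cx) % nx; if (bx < 0) bx += nx;
    int by = (int)std::floor(y / cy) % ny; if (by < 0) by += ny;
    int bz = (int)std::floor(z / cz) % nz; if (bz < 0) bz += nz;
    std::vector<int> seen;
    for (int dz = -1; dz <= 1; ++dz)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dx = -1; dx <= 1; ++dx) {
          int ux = (bx + dx + nx) % nx, uy = (by + dy + ny) % ny,
              uz = (bz + dz + nz) % nz;
          int c = (uz * ny + uy) * nx + ux;
          bool dup = false;
          for (int s : seen) if (s == c) { dup = true; break; }
          if (dup) continue;
          seen.push_back(c);
          for (int j = head[c]; j >= 0; j = nxt[j]) f(j);
        }
  }
};

// Geometric hydrogen-bond detection. donorIdx/hydIdx are parallel vectors
// of donor-hydrogen pairs (0-based atom indices); accIdx lists acceptor
// candidates. A bond is (donor, hydrogen, acceptor) with donor-acceptor
// distance <= maxDist and hydrogen-donor-acceptor angle <= maxAngleDeg.
// [[Rcpp::export(name = "hbond_detect_cpp")]]
IntegerMatrix hbond_detect_cpp(NumericMatrix coords, NumericVector box,
                               IntegerVector donorIdx, IntegerVector hydIdx,
                               IntegerVector accIdx, IntegerVector molId,
                               double maxDist, double maxAngleDeg,
                               bool excludeIntra) {
  int nPairs = donorIdx.size(), nAcc = accIdx.size();
  double cosMin = std::cos(maxAngleDeg * M_PI / 180.0);
  double d2max = maxDist * maxDist;

  CellGrid3 grid(box, maxDist, nAcc);
  for (int a = 0; a < nAcc; ++a) {
    int ia = accIdx[a];
    grid.insert(a, coords(ia, 0), coords(ia, 1), coords(ia, 2));
  }

  std::vector<int> outD, outH, outA;
  for (int p = 0; p < nPairs; ++p) {
    int id = donorIdx[p], ih = hydIdx[p];
    double dx0 = coords(id, 0), dy0 = coords(id, 1), dz0 = coords(id, 2);
    double hx = mi3(coords(ih, 0) - dx0, box[0]);
    double hy = mi3(coords(ih, 1) - dy0, box[1]);
    double hz = mi3(coords(ih, 2) - dz0, box[2]);
    double hn = std::sqrt(hx * hx + hy * hy + hz * hz);
    grid.forNeighbors(dx0, dy0, dz0, [&](int a) {
      int ia = accIdx[a];
      if (ia == id || ia == ih) return;
      if (excludeIntra && molId[ia] == molId[id]) return;
      double ax = mi3(coords(ia, 0) - dx0, box[0]);
      double ay = mi3(coords(ia, 1) - dy0, box[1]);
      double az = mi3(coords(ia, 2) - dz0, box[2]);
      double d2 = ax * ax + ay * ay + az * az;
      if (d2 > d2max || d2 < 1e-12) return;
      double an = std::sqrt(d2);
      double cosang = (hx * ax + hy * ay + hz * az) / (hn * an);
      if (cosang >= cosMin) {
        outD.push_back(id); outH.push_back(ih); outA.push_back(ia);
      }
    });
  }
  IntegerMatrix out(outD.size(), 3);
  for (size_t i = 0; i < outD.size(); ++i) {
    out(i, 0) = outD[i]; out(i, 1) = outH[i]; out(i, 2) = outA[i];
  }
  return out;
}

// Nonbonded cross-group energy: Coulomb + Lennard-Jones with
// Lorentz-Berthelot combination, plain distance cutoff, minimum image.
// Charges in e, sigma in nm, epsilon in kJ/mol, distances in nm.
// [[Rcpp::export(name = "pair_energy_cpp")]]
double pair_energy_cpp(NumericMatrix coords, NumericVector box,
                       IntegerVector idxA, IntegerVector idxB,
                       NumericVector q, NumericVector sigma,
                       NumericVector eps, double cutoff) {
  const double fke = 138.935458;  // kJ mol^-1 nm e^-2
  double c2 = cutoff * cutoff, E = 0.0;
  for (int a = 0; a < idxA.size(); ++a) {
    int i = idxA[a];
    for (int b = 0; b < idxB.size(); ++b) {
      int j = idxB[b];
      double dx = mi3(coords(i, 0) - coords(j, 0), box[0]);
      double dy = mi3(coords(i, 1) - coords(j, 1), box[1]);
      double dz = mi3(coords(i, 2) - coords(j, 2), box[2]);
      double r2 = dx * dx + dy * dy + dz * dz;
      if (r2 > c2) continue;
      if (r2 < 1e-6) stop("overlapping atoms (r < 1e-3 nm) in energy evaluation");
      double r = std::sqrt(r2);
      double sij = 0.5 * (sigma[i] + sigma[j]);
      double eij = std::sqrt(eps[i] * eps[j]);
      double sr6 = std::pow(sij * sij / r2, 3.0);
      E += fke * q[i] * q[j] / r + 4.0 * eij * (sr6 * sr6 - sr6);
    }
  }
  return E;
}

// Minimum distance between two atom groups (minimum image); used for the
// interacting-partner criterion without computing energies.
// [[Rcpp::export(name = "min_group_dist_cpp")]]
double min_group_dist_cpp(NumericMatrix coords, NumericVector box,
                          IntegerVector idxA, IntegerVector idxB) {
  double best = R_PosInf;
  for (int a = 0; a < idxA.size(); ++a) {
    int i = idxA[a];
    for (int b = 0; b < idxB.size(); ++b) {
      int j = idxB[b];
      double dx = mi3(coords(i, 0) - coords(j, 0), box[0]);
      double dy = mi3(coords(i, 1) - coords(j, 1), box[1]);
      double dz = mi3(coords(i, 2) - coords(j, 2), box[2]);
      double r2 = dx * dx + dy * dy + dz * dz;
      if (r2 < best) best = r2;
    }
  }
  return std::sqrt(best);
}
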