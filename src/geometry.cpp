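#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

// Minimum-image displacement on a 1-D torus of length L.
static inline double mi(double d, double L) {
  d -= L * std::round(d / L);
  return d;
}

static inline double wrap0(double x, double L) {
  x -= L * std::floor(x / L);
  if (x < 0) x += L;
  if (x >= L) x = 0.0;  // guard floating-point rounding
  return x;
}

// Linked-cell grid over 2-D points. Cell size is >= `range` so that all
// points within `range` of a query lie in the 3x3 cell neighbourhood.
struct CellGrid {
  int nc;
  double cell, L;
  std::vector<int> head, nxt;
  CellGrid(double L_, double range, int npts, int maxCells = 512)
      : L(L_) {
    nc = (int)std::floor(L_ / std::max(range, 1e-9));
    if (nc < 1) nc = 1;
    if (nc > maxCells) nc = maxCells;
    cell = L_ / nc;
    head.assign((size_t)nc * nc, -1);
    nxt.assign(npts, -1);
  }
  inline int cellIndex(double x, double y) const {
    int cx = (int)(x / cell); if (cx >= nc) cx = nc - 1;
    int cy = (int)(y / cell); if (cy >= nc) cy = nc - 1;
    return cy * nc + cx;
  }
  inline void insert(int i, double x, double y) {
    int c = cellIndex(x, y);
    nxt[i] = head[c];
    head[c] = i;
  }
  inline void remove(int i, double x, double y) {
    int c = cellIndex(x, y);
    int p = head[c];
    if (p == i) { head[c] = nxt[i]; return; }
    while (p >= 0 && nxt[p] != i) p = nxt[p];
    if (p >= 0) nxt[p] = nxt[i];
  }
  template <class F>
  inline void forNeighbors(double x, double y, F f) const {
    int cx = (int)(x / cell); if (cx >= nc) cx = nc - 1;
    int cy = (int)(y / cell); if (cy >= nc) cy = nc - 1;
    for (int dy = -1; dy <= 1; ++dy) {
      for (int dx = -1; dx <= 1; ++dx) {
        // callers fall back to all-pairs when nc <= 3, so the 3x3 block
        // visits each cell exactly once here
        int ux = (cx + dx + nc) % nc, uy = (cy + dy + nc) % nc;
        for (int j = head[uy * nc + ux]; j >= 0; j = nxt[j]) f(j);
      }
    }
  }
};

// For tiny grids (nc <= 3) the 3x3 neighbourhood may visit a cell twice;
// use an all-pairs fallback in the callers where that matters.

// Overlap "energy" of disc i at (x, y) against all other discs:
// sum of (2R - d)^2 over overlapping pairs.
static double discLocalEnergy(int i, double x, double y,
                              const std::vector<double>& px,
                              const std::vector<double>& py,
                              double R, double L, const CellGrid& grid,
                              bool smallGrid) {
  double e = 0.0, dmin = 2.0 * R, d2min = dmin * dmin;
  if (smallGrid) {
    int n = (int)px.size();
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      double dx = mi(x - px[j], L), dy = mi(y - py[j], L);
      double d2 = dx * dx + dy * dy;
      if (d2 < d2min) { double d = std::sqrt(d2); e += (dmin - d) * (dmin - d); }
    }
    return e;
  }
  std::vector<int> seen;
  grid.forNeighbors(x, y, [&](int j) {
    if (j == i) return;
    double dx = mi(x - px[j], L), dy = mi(y - py[j], L);
    double d2 = dx * dx + dy * dy;
    if (d2 < d2min) { double d = std::sqrt(d2); e += (dmin - d) * (dmin - d); }
  });
  return e;
}

// Equilibrated hard-disc configuration: start from a jittered square
// lattice (overlap-free by construction for the supported coverages,
// since the lattice constant L/m >= 2R whenever N*pi*R^2/L^2 <= 0.65 and
// L >= 10R), then run Metropolis displacement sweeps that reject any move
// creating an overlap. `maxSweeps` here is the number of shuffle sweeps.
// [[Rcpp::export(name = "place_discs_cpp")]]
NumericMatrix place_discs_cpp(int n, double R, double L, int maxSweeps) {
  if (n <= 0) return NumericMatrix(0, 2);
  if (2.0 * R > L / 2.0)
    stop("disc diameter exceeds half the box length");

  // Feasible periodic offset-row (triangular-like) lattice: nx columns of
  // spacing ax = L/nx, ny rows (even, for periodic consistency of the
  // half-column offset) of spacing ay = L/ny. Overlap-free when
  // ax >= 2R, 2*ay >= 2R and sqrt((ax/2)^2 + ay^2) >= 2R.
  const double D = 2.0 * R, tol = 1e-9;
  int nx = -1, ny = -1;
  for (int tx = (int)std::floor(L / D + tol); tx >= 1; --tx) {
    double ax = L / tx;
    int ty = (int)std::ceil((double)n / tx);
    ty += ty % 2;  // even
    if (ty < 2) ty = 2;
    double ay = L / ty;
    if (2.0 * ay + tol < D) continue;
    if (std::sqrt(0.25 * ax * ax + ay * ay) + tol < D) continue;
    nx = tx; ny = ty;
    break;
  }
  if (nx < 0)
    return NumericMatrix(0, 2);  // caller raises a descriptive error
  double ax = L / nx, ay = L / ny;

  // choose n of the nx*ny lattice sites at random (partial Fisher-Yates)
  int nsites = nx * ny;
  std::vector<int> sites(nsites);
  for (int i = 0; i < nsites; ++i) sites[i] = i;
  for (int i = 0; i < n; ++i) {
    int j = i + (int)(unif_rand() * (nsites - i));
    if (j >= nsites) j = nsites - 1;
    std::swap(sites[i], sites[j]);
  }
  std::vector<double> px(n), py(n);
  for (int i = 0; i < n; ++i) {
    int col = sites[i] % nx, row = sites[i] / nx;
    double off = (row % 2) ? 0.5 * ax : 0.0;
    px[i] = wrap0((col + 0.25) * ax + off, L);
    py[i] = wrap0((row + 0.5) * ay, L);
  }
  double jit = 0.0;  // randomization comes from site choice + shuffling

  CellGrid grid(L, 2.0 * R, n);
  bool smallGrid = grid.nc <= 3;
  if (!smallGrid)
    for (int i = 0; i < n; ++i) grid.insert(i, px[i], py[i]);

  // Metropolis shuffle: hard-core rejection randomizes the lattice order
  (void)jit;
  double delta = 0.5 * R;
  for (int sweep = 0; sweep < maxSweeps; ++sweep) {
    for (int t = 0; t < n; ++t) {
      int i = (int)(unif_rand() * n); if (i >= n) i = n - 1;
      double nx = wrap0(px[i] + (unif_rand() * 2.0 - 1.0) * delta, L);
      double ny = wrap0(py[i] + (unif_rand() * 2.0 - 1.0) * delta, L);
      if (discLocalEnergy(i, nx, ny, px, py, R, L, grid, smallGrid) > 0.0)
        continue;
      if (!smallGrid) grid.remove(i, px[i], py[i]);
      px[i] = nx; py[i] = ny;
      if (!smallGrid) grid.insert(i, nx, ny);
    }
  }
  NumericMatrix out(n, 2);
  for (int i = 0; i < n; ++i) { out(i, 0) = px[i]; out(i, 1) = py[i]; }
  return out;
}

// Minimum pairwise minimum-image distance of 2-D points (cell grid).
// [[Rcpp::export(name = "min_pair_dist_cpp")]]
double min_pair_dist_cpp(NumericMatrix pts, double L) {
  int n = pts.nrow();
  if (n < 2) return R_PosInf;
  double best2 = R_PosInf;
  // start from a generous range guess and fall back to all pairs for
  // small n; correctness only needs an upper bound on the true minimum
  if (n <= 64) {
    for (int i = 0; i < n; ++i)
      for (int j = i + 1; j < n; ++j) {
        double dx = mi(pts(i, 0) - pts(j, 0), L);
        double dy = mi(pts(i, 1) - pts(j, 1), L);
        double d2 = dx * dx + dy * dy;
        if (d2 < best2) best2 = d2;
      }
    return std::sqrt(best2);
  }
  // expected nearest-neighbour scale ~ L/sqrt(n); grow until a hit
  double range = 2.5 * L / std::sqrt((double)n);
  for (;;) {
    CellGrid grid(L, range, n);
    if (grid.nc <= 3) {  // degenerate: all pairs
      for (int i = 0; i < n; ++i)
        for (int j = i + 1; j < n; ++j) {
          double dx = mi(pts(i, 0) - pts(j, 0), L);
          double dy = mi(pts(i, 1) - pts(j, 1), L);
          double d2 = dx * dx + dy * dy;
          if (d2 < best2) best2 = d2;
        }
      return std::sqrt(best2);
    }
    for (int i = 0; i < n; ++i) grid.insert(i, pts(i, 0), pts(i, 1));
    best2 = R_PosInf;
    for (int i = 0; i < n; ++i) {
      grid.forNeighbors(pts(i, 0), pts(i, 1), [&](int j) {
        if (j <= i) return;
        double dx = mi(pts(i, 0) - pts(j, 0), L);
        double dy = mi(pts(i, 1) - pts(j, 1), L);
        double d2 = dx * dx + dy * dy;
        if (d2 < best2) best2 = d2;
      });
    }
    if (best2 <= range * range) return std::sqrt(best2);
    range *= 2.0;  // no pair within range: enlarge
    if (range >= L) {  // all pairs as last resort
      best2 = R_PosInf;
      for (int i = 0; i < n; ++i)
        for (int j = i + 1; j < n; ++j) {
          double dx = mi(pts(i, 0) - pts(j, 0), L);
          double dy = mi(pts(i, 1) - pts(j, 1), L);
          double d2 = dx * dx + dy * dy;
          if (d2 < best2) best2 = d2;
        }
      return std::sqrt(best2);
    }
  }
}

// [[Rcpp::export(name = "coverage_grid_cpp")]]
double coverage_grid_cpp(NumericMatrix centers, double R, double L, int nGrid) {
  int n = centers.nrow();
  if (n == 0) return 0.0;
  std::vector<char> covered((size_t)nGrid * nGrid, 0);
  double h = L / nGrid;
  int w = (int)std::ceil(R / h) + 1;
  for (int k = 0; k < n; ++k) {
    double cx = centers(k, 0), cy = centers(k, 1);
    int gx = (int)(cx / h), gy = (int)(cy / h);
    for (int dy = -w; dy <= w; ++dy) {
      for (int dx = -w; dx <= w; ++dx) {
        int ux = ((gx + dx) % nGrid + nGrid) % nGrid;
        int uy = ((gy + dy) % nGrid + nGrid) % nGrid;
        double x = (ux + 0.5) * h, y = (uy + 0.5) * h;
        double ddx = mi(x - cx, L), ddy = mi(y - cy, L);
        if (ddx * ddx + ddy * ddy <= R * R) covered[(size_t)uy * nGrid + ux] = 1;
      }
    }
  }
  long cnt = 0;
  for (size_t i = 0; i < covered.size(); ++i) cnt += covered[i];
  return (double)cnt / ((double)nGrid * nGrid);
}

static inline bool inDomain(double x, double y, const NumericMatrix& centers,
                            double R, double L) {
  int n = centers.nrow();
  for (int k = 0; k < n; ++k) {
    double dx = mi(x - centers(k, 0), L), dy = mi(y - centers(k, 1), L);
    if (dx * dx + dy * dy <= R * R) return true;
  }
  return false;
}

// [[Rcpp::export(name = "place_probes_cpp")]]
List place_probes_cpp(NumericMatrix centers, double R, double L,
                      int nD, int nA, double pD, double pA,
                      double rMin, double dz) {
  NumericMatrix dXY(nD, 2), aXY(nA, 2);
  IntegerVector dLeaf(nD), aLeaf(nA);
  LogicalVector dIn(nD), aIn(nA);

  // domain membership tested against all discs when few, cell grid when many
  int ncent = centers.nrow();
  CellGrid* cgrid = nullptr;
  bool useGrid = ncent > 16;
  std::vector<double> cx(ncent), cy(ncent);
  if (useGrid) {
    cgrid = new CellGrid(L, 2.0 * R, ncent);
    if (cgrid->nc <= 3) { useGrid = false; delete cgrid; cgrid = nullptr; }
    else {
      for (int k = 0; k < ncent; ++k) {
        cx[k] = centers(k, 0); cy[k] = centers(k, 1);
        cgrid->insert(k, cx[k], cy[k]);
      }
    }
  }
  auto isIn = [&](double x, double y) {
    if (!useGrid) return inDomain(x, y, centers, R, L);
    bool found = false;
    cgrid->forNeighbors(x, y, [&](int k) {
      if (found) return;
      double ddx = mi(x - cx[k], L), ddy = mi(y - cy[k], L);
      if (ddx * ddx + ddy * ddy <= R * R) found = true;
    });
    return found;
  };

  const long maxTry = 20000000L;
  long tries = 0;
  auto drawInPhase = [&](bool wantIn, double& x, double& y) {
    for (;;) {
      if (++tries > maxTry) stop("probe placement failed: rejection sampling did not terminate (phase area too small?)");
      x = unif_rand() * L; y = unif_rand() * L;
      if (isIn(x, y) == wantIn) return;
    }
  };

  for (int i = 0; i < nD; ++i) {
    bool wantIn = ncent > 0 && unif_rand() < pD;
    double x, y;
    drawInPhase(wantIn, x, y);
    dXY(i, 0) = x; dXY(i, 1) = y;
    dLeaf[i] = (i < nD / 2) ? 0 : 1;
    dIn[i] = wantIn;
  }

  // donor grid for the excluded-distance check
  CellGrid dgrid(L, std::max(rMin, 1e-6), nD);
  bool dSmall = dgrid.nc <= 3 || rMin <= 0;
  if (!dSmall)
    for (int i = 0; i < nD; ++i) dgrid.insert(i, dXY(i, 0), dXY(i, 1));
  double dz2 = dz * dz, r2 = rMin * rMin;
  auto tooClose = [&](double x, double y, int leaf) {
    if (rMin <= 0) return false;
    bool bad = false;
    auto check = [&](int j) {
      if (bad) return;
      double ddx = mi(x - dXY(j, 0), L), ddy = mi(y - dXY(j, 1), L);
      double dlat2 = ddx * ddx + ddy * ddy;
      double dd2 = (dLeaf[j] == leaf) ? dlat2 : dlat2 + dz2;
      if (dd2 < r2) bad = true;
    };
    if (dSmall) { for (int j = 0; j < nD; ++j) check(j); }
    else dgrid.forNeighbors(x, y, check);
    return bad;
  };

  for (int i = 0; i < nA; ++i) {
    bool wantIn = ncent > 0 && unif_rand() < pA;
    int leaf = (i < nA / 2) ? 0 : 1;
    double x, y;
    for (;;) {
      drawInPhase(wantIn, x, y);
      if (!tooClose(x, y, leaf)) break;
    }
    aXY(i, 0) = x; aXY(i, 1) = y;
    aLeaf[i] = leaf;
    aIn[i] = wantIn;
  }
  if (cgrid) delete cgrid;
  return List::create(_["donorXY"] = dXY, _["donorLeaflet"] = dLeaf,
                      _["donorInDomain"] = dIn,
                      _["acceptorXY"] = aXY, _["acceptorLeaflet"] = aLeaf,
                      _["acceptorInDomain"] = aIn);
}

// Sum of (R0/r)^6 over acceptors for every donor. `cutoff` <= 0 means
// exact all-pairs; otherwise acceptors beyond the cutoff contribute a
// mean-field tail 2*pi*sigma*R0^6/(4*cutoff^4) using the average
// acceptor density.
// [[Rcpp::export(name = "rate_sums_cpp")]]
NumericVector rate_sums_cpp(NumericMatrix dXY, IntegerVector dLeaf,
                            NumericMatrix aXY, IntegerVector aLeaf,
                            double L, double dz, double R0, double rMin,
                            double cutoff) {
  int nD = dXY.nrow(), nA = aXY.nrow();
  NumericVector s(nD);
  double R06 = std::pow(R0, 6.0), dz2 = dz * dz, r2min = rMin * rMin;
  bool exact = cutoff <= 0 || cutoff >= L / 2.0;
  double c2 = cutoff * cutoff;

  auto accum = [&](int i, int j, double& acc) {
    double dx = mi(dXY(i, 0) - aXY(j, 0), L), dy = mi(dXY(i, 1) - aXY(j, 1), L);
    double d2 = dx * dx + dy * dy;
    if (dLeaf[i] != aLeaf[j]) d2 += dz2;
    if (d2 < r2min) stop("donor-acceptor pair closer than rMin");
    if (exact || d2 <= c2) acc += R06 / (d2 * d2 * d2);
  };

  if (exact || nA < 64) {
    for (int i = 0; i < nD; ++i) {
      double acc = 0.0;
      for (int j = 0; j < nA; ++j) accum(i, j, acc);
      if (!exact) acc += 2.0 * M_PI * (nA / (L * L)) * R06 / (4.0 * c2 * c2);
      s[i] = acc;
    }
    return s;
  }

  CellGrid grid(L, cutoff, nA);
  bool small = grid.nc <= 3;
  if (!small)
    for (int j = 0; j < nA; ++j) grid.insert(j, aXY(j, 0), aXY(j, 1));
  double tail = 2.0 * M_PI * (nA / (L * L)) * R06 / (4.0 * c2 * c2);
  for (int i = 0; i < nD; ++i) {
    double acc = 0.0;
    if (small) {
      for (int j = 0; j < nA; ++j) accum(i, j, acc);
    } else {
      grid.forNeighbors(dXY(i, 0), dXY(i, 1), [&](int j) { accum(i, j, acc); });
    }
    s[i] = acc + tail;
  }
  return s;
}

// Donor-ensemble decay F(x_k) = mean_i exp(-x_k * (1 + s_i)), x = t/tauD.
// Exact for small ensembles; for large ones the s distribution is
// compressed into equal-count bins (bin-mean representative), which is
// accurate to well below Monte-Carlo noise for >= 1024 bins.
// [[Rcpp::export(name = "decay_from_rates_cpp")]]
NumericVector decay_from_rates_cpp(NumericVector s, NumericVector x,
                                   int exactMax, int nBins) {
  int n = s.size(), nt = x.size();
  NumericVector F(nt);
  std::vector<double> rep; std::vector<double> w;
  if (n <= exactMax) {
    rep.assign(s.begin(), s.end());
    w.assign(n, 1.0 / n);
  } else {
    std::vector<double> ss(s.begin(), s.end());
    std::sort(ss.begin(), ss.end());
    int nb = std::min(nBins, n);
    rep.reserve(nb); w.reserve(nb);
    for (int b = 0; b < nb; ++b) {
      size_t lo = (size_t)((double)b * n / nb), hi = (size_t)((double)(b + 1) * n / nb);
      if (hi <= lo) continue;
      double m = 0.0;
      for (size_t i = lo; i < hi; ++i) m += ss[i];
      rep.push_back(m / (hi - lo));
      w.push_back((double)(hi - lo) / n);
    }
  }
  for (int k = 0; k < nt; ++k) {
    double acc = 0.0, xk = x[k];
    for (size_t b = 0; b < rep.size(); ++b)
      acc += w[b] * std::exp(-xk * (1.0 + rep[b]));
    F[k] = acc;
  }
  return F;
}
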