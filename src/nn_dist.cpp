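#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <limits>
using namespace Rcpp;

// Nearest-neighbour Euclidean distances from each row of `from` to the
// point set `to` (both n x 3, mm), using a uniform-grid spatial index over
// `to`. Exact: a shell at Chebyshev cell radius r around the query's
// (clamped) cell can only contain points at distance >= (r-1)*cell, so the
// search stops once that bound exceeds the best distance found.
// [[Rcpp::export(name = ".nn_point_distances")]]
NumericVector nn_point_distances(NumericMatrix from, NumericMatrix to,
                                 double cell = 4.0) {
  const int nq = from.nrow(), np = to.nrow();
  NumericVector out(nq);
  if (np == 0) {
    std::fill(out.begin(), out.end(), R_PosInf);
    return out;
  }
  if (cell <= 0) stop("cell size must be positive");

  // flat copies for fast access
  std::vector<double> tx(np), ty(np), tz(np);
  for (int i = 0; i < np; ++i) {
    tx[i] = to(i, 0); ty[i] = to(i, 1); tz[i] = to(i, 2);
  }

  double lo[3], hi[3];
  for (int a = 0; a < 3; ++a) { lo[a] = R_PosInf; hi[a] = R_NegInf; }
  for (int i = 0; i < np; ++i) {
    const double v[3] = {tx[i], ty[i], tz[i]};
    for (int a = 0; a < 3; ++a) {
      if (v[a] < lo[a]) lo[a] = v[a];
      if (v[a] > hi[a]) hi[a] = v[a];
    }
  }
  int nc[3];
  for (int a = 0; a < 3; ++a) {
    nc[a] = (int)std::floor((hi[a] - lo[a]) / cell) + 1;
    if (nc[a] < 1) nc[a] = 1;
  }
  const int ncells = nc[0] * nc[1] * nc[2];

  // counting-sort points into cells
  std::vector<int> cellof(np), count(ncells + 1, 0);
  for (int i = 0; i < np; ++i) {
    int c[3];
    const double v[3] = {tx[i], ty[i], tz[i]};
    for (int a = 0; a < 3; ++a) {
      int k = (int)std::floor((v[a] - lo[a]) / cell);
      if (k < 0) k = 0;
      if (k >= nc[a]) k = nc[a] - 1;
      c[a] = k;
    }
    cellof[i] = c[0] + nc[0] * (c[1] + nc[1] * c[2]);
    ++count[cellof[i] + 1];
  }
  for (int c = 0; c < ncells; ++c) count[c + 1] += count[c];
  std::vector<int> order(np), fill(count.begin(), count.end() - 1);
  for (int i = 0; i < np; ++i) order[fill[cellof[i]]++] = i;

  const int maxr = std::max(std::max(nc[0], nc[1]), nc[2]);
  for (int q = 0; q < nq; ++q) {
    const double qx = from(q, 0), qy = from(q, 1), qz = from(q, 2);
    int qc[3];
    {
      const double qv[3] = {qx, qy, qz};
      for (int a = 0; a < 3; ++a) {
        int k = (int)std::floor((qv[a] - lo[a]) / cell);
        if (k < 0) k = 0;
        if (k >= nc[a]) k = nc[a] - 1;
        qc[a] = k;
      }
    }
    double best2 = std::numeric_limits<double>::infinity();
    for (int r = 0; r <= maxr; ++r) {
      if (best2 < std::numeric_limits<double>::infinity()) {
        double lb = (double)(r - 1) * cell;
        if (lb > 0 && lb * lb > best2) break;
      }
      const int x0 = std::max(qc[0] - r, 0), x1 = std::min(qc[0] + r, nc[0] - 1);
      const int y0 = std::max(qc[1] - r, 0), y1 = std::min(qc[1] + r, nc[1] - 1);
      const int z0 = std::max(qc[2] - r, 0), z1 = std::min(qc[2] + r, nc[2] - 1);
      for (int cz = z0; cz <= z1; ++cz)
        for (int cy = y0; cy <= y1; ++cy)
          for (int cx = x0; cx <= x1; ++cx) {
            // only the shell at Chebyshev radius exactly r
            int dr = std::max(std::max(std::abs(cx - qc[0]),
                                       std::abs(cy - qc[1])),
                              std::abs(cz - qc[2]));
            if (dr != r) continue;
            const int cid = cx + nc[0] * (cy + nc[1] * cz);
            for (int t = count[cid]; t < count[cid + 1]; ++t) {
              const int i = order[t];
              const double dx = tx[i] - qx, dy = ty[i] - qy,
                           dz = tz[i] - qz;
              const double d2 = dx * dx + dy * dy + dz * dz;
              if (d2 < best2) best2 = d2;
            }
          }
    }
    out[q] = std::sqrt(best2);
  }
  return out;
}
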