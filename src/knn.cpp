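#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <algorithm>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

// Mean distance from each point to its k nearest neighbours, via a uniform
// grid hash with expanding ring search. Points are not their own neighbour.
// [[Rcpp::export]]
NumericVector cpp_knn_mean_dist(NumericMatrix pts, int k) {
  const int n = pts.nrow();
  NumericVector out(n);
  if (n == 0) return out;

  double lo[3], hi[3];
  for (int d = 0; d < 3; ++d) {
    lo[d] = pts(0, d);
    hi[d] = pts(0, d);
  }
  for (int i = 1; i < n; ++i)
    for (int d = 0; d < 3; ++d) {
      if (pts(i, d) < lo[d]) lo[d] = pts(i, d);
      if (pts(i, d) > hi[d]) hi[d] = pts(i, d);
    }
  double ext[3], vol = 1.0, maxext = 0.0;
  for (int d = 0; d < 3; ++d) {
    ext[d] = hi[d] - lo[d];
    if (ext[d] > maxext) maxext = ext[d];
  }
  if (maxext <= 0) maxext = 1.0;
  for (int d = 0; d < 3; ++d) vol *= (ext[d] > 1e-9 * maxext ? ext[d] : 0.05 * maxext);
  // start from a volumetric guess, then shrink the cell until the mean
  // occupancy of occupied cells is modest: point clouds of surfaces (ground,
  // canopies) concentrate points far above the volumetric density, and
  // oversized cells make the ring search quadratic
  double cell = std::cbrt(vol * std::max(k, 1) / std::max(n, 1));
  if (!(cell > 0)) cell = maxext / std::cbrt((double)n);
  if (!(cell > 0)) cell = 1.0;

  int dim[3];
  std::unordered_map<int64_t, std::vector<int> > grid;
  std::vector<int> ci(n), cj(n), ck(n);
  double target_occ = std::max(4.0, k / 4.0);
  for (int pass = 0; pass < 12; ++pass) {
    for (int d = 0; d < 3; ++d) {
      dim[d] = (int)std::floor(ext[d] / cell) + 1;
      if (dim[d] < 1) dim[d] = 1;
    }
    grid.clear();
    grid.reserve(n);
    for (int i = 0; i < n; ++i) {
      int a = (int)std::floor((pts(i, 0) - lo[0]) / cell);
      int b = (int)std::floor((pts(i, 1) - lo[1]) / cell);
      int c = (int)std::floor((pts(i, 2) - lo[2]) / cell);
      if (a >= dim[0]) a = dim[0] - 1;
      if (b >= dim[1]) b = dim[1] - 1;
      if (c >= dim[2]) c = dim[2] - 1;
      ci[i] = a; cj[i] = b; ck[i] = c;
      int64_t key = ((int64_t)a * dim[1] + b) * dim[2] + c;
      grid[key].push_back(i);
    }
    double occ = (double)n / (double)grid.size();
    if (occ <= target_occ || cell <= 1e-9 * maxext) break;
    cell /= 1.7;
  }

  std::vector<double> d2;
  d2.reserve(8 * (size_t)k + 64);
  int rmax = std::max(std::max(dim[0], dim[1]), dim[2]);
  for (int i = 0; i < n; ++i) {
    d2.clear();
    double px = pts(i, 0), py = pts(i, 1), pz = pts(i, 2);
    double kth = R_PosInf;
    for (int r = 0; r <= rmax; ++r) {
      // collect the ring of cells at Chebyshev radius r
      int alo = std::max(ci[i] - r, 0), ahi = std::min(ci[i] + r, dim[0] - 1);
      int blo = std::max(cj[i] - r, 0), bhi = std::min(cj[i] + r, dim[1] - 1);
      int clo = std::max(ck[i] - r, 0), chi = std::min(ck[i] + r, dim[2] - 1);
      for (int a = alo; a <= ahi; ++a)
        for (int b = blo; b <= bhi; ++b)
          for (int c = clo; c <= chi; ++c) {
            int cheb = std::max(std::max(std::abs(a - ci[i]), std::abs(b - cj[i])),
                                std::abs(c - ck[i]));
            if (cheb != r) continue;  // only the new shell
            int64_t key = ((int64_t)a * dim[1] + b) * dim[2] + c;
            std::unordered_map<int64_t, std::vector<int> >::iterator it =
              grid.find(key);
            if (it == grid.end()) continue;
            const std::vector<int>& cellpts = it->second;
            for (size_t m = 0; m < cellpts.size(); ++m) {
              int j = cellpts[m];
              if (j == i) continue;
              double dx = pts(j, 0) - px, dy = pts(j, 1) - py,
                     dz = pts(j, 2) - pz;
              d2.push_back(dx * dx + dy * dy + dz * dz);
            }
          }
      if ((int)d2.size() >= k) {
        std::nth_element(d2.begin(), d2.begin() + (k - 1), d2.end());
        kth = d2[k - 1];
        // all points within distance r*cell of the query are already seen
        double guaranteed = (double)r * cell;
        if (kth <= guaranteed * guaranteed) break;
      }
    }
    if ((int)d2.size() < k) {
      out[i] = NA_REAL;  // caller guarantees k < n, should not happen
      continue;
    }
    std::partial_sort(d2.begin(), d2.begin() + k, d2.end());
    double s = 0.0;
    for (int m = 0; m < k; ++m) s += std::sqrt(d2[m]);
    out[i] = s / k;
  }
  return out;
}
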