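#include <Rcpp.h>
#include <vector>
#include <queue>
using namespace Rcpp;

// Exact farthest pair among a point cloud (mm coordinates), O(n^2).
// Used on boundary voxels only, so n stays in the low tens of thousands.
// [[Rcpp::export]]
List farthest_pair_cpp(NumericMatrix pts) {
  int n = pts.nrow();
  if (n < 1) stop("empty point set");
  double best = -1.0;
  int bi = 0, bj = 0;
  for (int i = 0; i < n; ++i) {
    double xi = pts(i, 0), yi = pts(i, 1), zi = pts(i, 2);
    for (int j = i + 1; j < n; ++j) {
      double dx = pts(j, 0) - xi, dy = pts(j, 1) - yi, dz = pts(j, 2) - zi;
      double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 > best) { best = d2; bi = i; bj = j; }
    }
  }
  if (n == 1) { best = 0.0; bi = bj = 0; }
  return List::create(_["d"] = std::sqrt(best < 0 ? 0.0 : best),
                      _["i"] = bi + 1, _["j"] = bj + 1);
}

// 6-connected component labelling of a binary 3D array.
// [[Rcpp::export]]
IntegerVector label_components_cpp(IntegerVector occ, IntegerVector dims) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  int n = nx * ny * nz;
  IntegerVector lab(n, 0);
  int cur = 0;
  std::vector<int> stack;
  const int dx[6] = {1, -1, 0, 0, 0, 0};
  const int dy[6] = {0, 0, 1, -1, 0, 0};
  const int dz[6] = {0, 0, 0, 0, 1, -1};
  for (int idx = 0; idx < n; ++idx) {
    if (occ[idx] == 0 || lab[idx] != 0) continue;
    ++cur;
    stack.push_back(idx);
    lab[idx] = cur;
    while (!stack.empty()) {
      int p = stack.back(); stack.pop_back();
      int x = p % nx, y = (p / nx) % ny, z = p / (nx * ny);
      for (int k = 0; k < 6; ++k) {
        int xx = x + dx[k], yy = y + dy[k], zz = z + dz[k];
        if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
          continue;
        int q = xx + nx * (yy + ny * zz);
        if (occ[q] != 0 && lab[q] == 0) { lab[q] = cur; stack.push_back(q); }
      }
    }
  }
  lab.attr("dim") = dims;
  return lab;
}
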