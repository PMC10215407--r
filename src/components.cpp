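// 3D connected-component labeling by breadth-first search.
// Connectivity 6/18/26 (face / face+edge / full neighborhood). 2D labeling
// reuses the same kernel with a single-slice volume (6 -> 4-connectivity
// in-plane, 26 -> 8-connectivity).
#include <Rcpp.h>
#include <vector>
#include <queue>
using namespace Rcpp;

// [[Rcpp::export]]
List label_components_cpp(IntegerVector mask, IntegerVector dims,
                          int connectivity) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  if (mask.size() != n) stop("mask/dims mismatch");
  int reach;
  switch (connectivity) {
    case 6: reach = 1; break;
    case 18: reach = 2; break;
    case 26: reach = 3; break;
    default: stop("connectivity must be 6, 18 or 26");
  }
  std::vector<std::array<int, 3>> offs;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        int m = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (m > 0 && m <= reach) offs.push_back({dx, dy, dz});
      }

  IntegerVector labels(n, 0);
  std::vector<double> counts;
  int next_label = 0;
  std::queue<R_xlen_t> q;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (mask[s] == 0 || labels[s] != 0) continue;
    ++next_label;
    double cnt = 0;
    labels[s] = next_label;
    q.push(s);
    while (!q.empty()) {
      R_xlen_t cur = q.front(); q.pop();
      ++cnt;
      int x = (int)(cur % nx);
      int y = (int)((cur / nx) % ny);
      int z = (int)(cur / ((R_xlen_t)nx * ny));
      for (const auto &o : offs) {
        int xx = x + o[0], yy = y + o[1], zz = z + o[2];
        if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
          continue;
        R_xlen_t idx = xx + (R_xlen_t)nx * (yy + (R_xlen_t)ny * zz);
        if (mask[idx] != 0 && labels[idx] == 0) {
          labels[idx] = next_label;
          q.push(idx);
        }
      }
    }
    counts.push_back(cnt);
  }
  labels.attr("dim") = dims;
  return List::create(_["labels"] = labels,
                      _["counts"] = NumericVector(counts.begin(), counts.end()),
                      _["connectivity"] = connectivity);
}
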