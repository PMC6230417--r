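#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Build neighbor offsets for 6/18/26-connectivity in 3-D.
static std::vector<std::array<int, 3>> neighbor_offsets(int connectivity) {
  std::vector<std::array<int, 3>> off;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        int l1 = std::abs(dz) + std::abs(dy) + std::abs(dx);
        if (l1 == 0) continue;
        if (connectivity == 6 && l1 > 1) continue;
        if (connectivity == 18 && l1 > 2) continue;
        off.push_back({dz, dy, dx});
      }
  return off;
}

// Label connected components of a 3-D logical array (column-major,
// dim = c(d1, d2, d3) with axis 1 fastest). Background = 0, components
// numbered from 1 in scan order.
// [[Rcpp::export]]
IntegerVector label_components_cpp(LogicalVector mask, IntegerVector dim,
                                   int connectivity) {
  const int d1 = dim[0], d2 = dim[1], d3 = dim[2];
  const R_xlen_t n = (R_xlen_t)d1 * d2 * d3;
  if (mask.size() != n) stop("mask length does not match dim");
  if (connectivity != 6 && connectivity != 18 && connectivity != 26)
    stop("connectivity must be 6, 18 or 26");
  const auto off = neighbor_offsets(connectivity);

  IntegerVector labels(n, 0);
  std::vector<R_xlen_t> stack;
  int next = 0;
  for (R_xlen_t i = 0; i < n; ++i) {
    if (!mask[i] || labels[i] != 0) continue;
    ++next;
    labels[i] = next;
    stack.push_back(i);
    while (!stack.empty()) {
      R_xlen_t p = stack.back();
      stack.pop_back();
      int z = (int)(p % d1);
      int y = (int)((p / d1) % d2);
      int x = (int)(p / ((R_xlen_t)d1 * d2));
      for (const auto &o : off) {
        int zz = z + o[0], yy = y + o[1], xx = x + o[2];
        if (zz < 0 || zz >= d1 || yy < 0 || yy >= d2 || xx < 0 || xx >= d3)
          continue;
        R_xlen_t q = zz + (R_xlen_t)d1 * (yy + (R_xlen_t)d2 * xx);
        if (mask[q] && labels[q] == 0) {
          labels[q] = next;
          stack.push_back(q);
        }
      }
    }
  }
  labels.attr("n_components") = next;
  return labels;
}
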