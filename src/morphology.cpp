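#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Voxel offsets of a Euclidean ball of the given radius (in voxels).
static std::vector<std::array<int, 3>> ball_offsets(int radius) {
  std::vector<std::array<int, 3>> off;
  int r2 = radius * radius;
  for (int dz = -radius; dz <= radius; ++dz)
    for (int dy = -radius; dy <= radius; ++dy)
      for (int dx = -radius; dx <= radius; ++dx)
        if (dz * dz + dy * dy + dx * dx <= r2) off.push_back({dz, dy, dx});
  return off;
}

// Binary dilation (op = 0) or erosion (op = 1) with a ball structuring
// element. Out-of-grid voxels count as background for dilation and as
// foreground for erosion, so that closing is extensive and opening
// anti-extensive on the bounded grid.
// [[Rcpp::export]]
LogicalVector binary_morph_cpp(LogicalVector mask, IntegerVector dim,
                               int radius, int op) {
  const int d1 = dim[0], d2 = dim[1], d3 = dim[2];
  const R_xlen_t n = (R_xlen_t)d1 * d2 * d3;
  if (mask.size() != n) stop("mask length does not match dim");
  if (radius < 0) stop("radius must be >= 0");
  if (radius == 0) return clone(mask);
  const auto off = ball_offsets(radius);

  LogicalVector out(n);
  for (int x = 0; x < d3; ++x)
    for (int y = 0; y < d2; ++y)
      for (int z = 0; z < d1; ++z) {
        R_xlen_t p = z + (R_xlen_t)d1 * (y + (R_xlen_t)d2 * x);
        bool res = (op == 1); // erosion: all; dilation: any
        for (const auto &o : off) {
          int zz = z + o[0], yy = y + o[1], xx = x + o[2];
          if (zz < 0 || zz >= d1 || yy < 0 || yy >= d2 || xx < 0 || xx >= d3)
            continue; // outside: false for dilation, true for erosion
          bool v = mask[zz + (R_xlen_t)d1 * (yy + (R_xlen_t)d2 * xx)];
          if (op == 0 && v) { res = true; break; }
          if (op == 1 && !v) { res = false; break; }
        }
        out[p] = res;
      }
  return out;
}
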