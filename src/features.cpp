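#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Per-voxel texture features over cubic neighborhoods.
//
// For every ROI voxel the window x window x window neighborhood (clipped at
// the grid border) contributes:
//   statistical: mean, population sd, moment skewness, excess kurtosis,
//                median of the raw HU values;
//   GLCM:        contrast, correlation, entropy (bits), energy, homogeneity
//                of the symmetric co-occurrence matrix of the quantized
//                values, pooled over the supplied offsets; pairs are counted
//                only when both ends lie inside the clipped neighborhood.
// Zero-variance neighborhoods get skewness = kurtosis = 0 and GLCM
// correlation = 0 (documented conventions).
//
// hu: raw HU values, q: quantized levels in [0, levels), both column-major
// with dim = (d1, d2, d3), axis 1 fastest. offsets: one (dz, dy, dx) per row.
// Returns an n x 13 matrix: 1-based (z, y, x) then the 10 features.
// [[Rcpp::export]]
NumericMatrix feature_map_cpp(NumericVector hu, IntegerVector q,
                              IntegerVector dim, LogicalVector roi,
                              int window, int levels,
                              IntegerMatrix offsets) {
  const int d1 = dim[0], d2 = dim[1], d3 = dim[2];
  const R_xlen_t n = (R_xlen_t)d1 * d2 * d3;
  if (hu.size() != n || q.size() != n || roi.size() != n)
    stop("array lengths do not match dim");
  if (window < 1 || window % 2 == 0) stop("window must be odd and >= 1");
  const int h = window / 2;
  const int L = levels;
  const int no = offsets.nrow();

  R_xlen_t nroi = 0;
  for (R_xlen_t i = 0; i < n; ++i) if (roi[i]) ++nroi;
  NumericMatrix out(nroi, 13);

  std::vector<double> glcm((size_t)L * L);
  std::vector<double> buf;
  buf.reserve((size_t)window * window * window);
  std::vector<double> pi(L), pj(L);

  R_xlen_t row = 0;
  for (R_xlen_t p = 0; p < n; ++p) {
    if (!roi[p]) continue;
    int z = (int)(p % d1);
    int y = (int)((p / d1) % d2);
    int x = (int)(p / ((R_xlen_t)d1 * d2));
    int z0 = std::max(0, z - h), z1 = std::min(d1 - 1, z + h);
    int y0 = std::max(0, y - h), y1 = std::min(d2 - 1, y + h);
    int x0 = std::max(0, x - h), x1 = std::min(d3 - 1, x + h);

    // --- statistical features on raw HU ---
    buf.clear();
    double s = 0.0;
    for (int xx = x0; xx <= x1; ++xx)
      for (int yy = y0; yy <= y1; ++yy)
        for (int zz = z0; zz <= z1; ++zz) {
          double v = hu[zz + (R_xlen_t)d1 * (yy + (R_xlen_t)d2 * xx)];
          buf.push_back(v);
          s += v;
        }
    const double m = s / buf.size();
    double m2 = 0, m3 = 0, m4 = 0;
    for (double v : buf) {
      double d = v - m, d2_ = d * d;
      m2 += d2_; m3 += d2_ * d; m4 += d2_ * d2_;
    }
    m2 /= buf.size(); m3 /= buf.size(); m4 /= buf.size();
    double sd = std::sqrt(m2);
    double skew = m2 > 0 ? m3 / std::pow(m2, 1.5) : 0.0;
    double kurt = m2 > 0 ? m4 / (m2 * m2) - 3.0 : 0.0;
    double med;
    {
      size_t k = buf.size() / 2;
      std::nth_element(buf.begin(), buf.begin() + k, buf.end());
      med = buf[k];
      if (buf.size() % 2 == 0) {
        double lo = *std::max_element(buf.begin(), buf.begin() + k);
        med = (med + lo) / 2.0;
      }
    }

    // --- GLCM over the clipped neighborhood ---
    std::fill(glcm.begin(), glcm.end(), 0.0);
    double total = 0.0;
    for (int io = 0; io < no; ++io) {
      int oz = offsets(io, 0), oy = offsets(io, 1), ox = offsets(io, 2);
      for (int xx = x0; xx <= x1; ++xx) {
        int xb = xx + ox; if (xb < x0 || xb > x1) continue;
        for (int yy = y0; yy <= y1; ++yy) {
          int yb = yy + oy; if (yb < y0 || yb > y1) continue;
          for (int zz = z0; zz <= z1; ++zz) {
            int zb = zz + oz; if (zb < z0 || zb > z1) continue;
            int a = q[zz + (R_xlen_t)d1 * (yy + (R_xlen_t)d2 * xx)];
            int b = q[zb + (R_xlen_t)d1 * (yb + (R_xlen_t)d2 * xb)];
            glcm[(size_t)a * L + b] += 1.0; // symmetric: count both orders
            glcm[(size_t)b * L + a] += 1.0;
            total += 2.0;
          }
        }
      }
    }
    double contrast = 0, entropy = 0, energy = 0, homog = 0, corr = 0;
    if (total > 0) {
      std::fill(pi.begin(), pi.end(), 0.0);
      std::fill(pj.begin(), pj.end(), 0.0);
      for (int i = 0; i < L; ++i)
        for (int j = 0; j < L; ++j) {
          double pr = glcm[(size_t)i * L + j] / total;
          if (pr == 0) continue;
          contrast += pr * (i - j) * (i - j);
          entropy -= pr * std::log2(pr);
          energy += pr * pr;
          homog += pr / (1.0 + std::abs(i - j));
          pi[i] += pr;
          pj[j] += pr;
        }
      double mi = 0, mj = 0;
      for (int i = 0; i < L; ++i) { mi += i * pi[i]; mj += i * pj[i]; }
      double vi = 0, vj = 0;
      for (int i = 0; i < L; ++i) {
        vi += (i - mi) * (i - mi) * pi[i];
        vj += (i - mj) * (i - mj) * pj[i];
      }
      double denom = std::sqrt(vi) * std::sqrt(vj);
      if (denom > 0) {
        double cov = 0;
        for (int i = 0; i < L; ++i)
          for (int j = 0; j < L; ++j) {
            double pr = glcm[(size_t)i * L + j] / total;
            if (pr > 0) cov += (i - mi) * (j - mj) * pr;
          }
        corr = cov / denom;
      }
    }

    out(row, 0) = z + 1; out(row, 1) = y + 1; out(row, 2) = x + 1;
    out(row, 3) = m; out(row, 4) = sd; out(row, 5) = skew;
    out(row, 6) = kurt; out(row, 7) = med;
    out(row, 8) = contrast; out(row, 9) = corr; out(row, 10) = entropy;
    out(row, 11) = energy; out(row, 12) = homog;
    ++row;
  }
  return out;
}
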