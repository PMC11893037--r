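#include <Rcpp.h>
#include <cmath>
#include <queue>
using namespace Rcpp;

static inline double clampd(double x, double lo, double hi) {
  return x < lo ? lo : (x > hi ? hi : x);
}

// Trilinear sampling of a 3D volume at arbitrary 0-based voxel coordinates.
// Out-of-grid samples clamp to the nearest edge.
// [[Rcpp::export]]
NumericVector cpp_trilinear(NumericVector vol, IntegerVector dims,
                            NumericMatrix pts) {
  const int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  const int M = pts.nrow();
  NumericVector out(M);
  for (int m = 0; m < M; ++m) {
    double x = clampd(pts(m, 0), 0.0, n1 - 1.0);
    double y = clampd(pts(m, 1), 0.0, n2 - 1.0);
    double z = clampd(pts(m, 2), 0.0, n3 - 1.0);
    int x0 = (int)std::floor(x), y0 = (int)std::floor(y), z0 = (int)std::floor(z);
    if (x0 > n1 - 2) x0 = n1 - 2;
    if (y0 > n2 - 2) y0 = n2 - 2;
    if (z0 > n3 - 2) z0 = n3 - 2;
    if (x0 < 0) x0 = 0;
    if (y0 < 0) y0 = 0;
    if (z0 < 0) z0 = 0;
    const double fx = x - x0, fy = y - y0, fz = z - z0;
    double acc = 0.0;
    for (int c = 0; c <= 1; ++c) {
      const double wz = c ? fz : 1.0 - fz;
      for (int b = 0; b <= 1; ++b) {
        const double wyz = (b ? fy : 1.0 - fy) * wz;
        const R_xlen_t base = (R_xlen_t)((z0 + c) * n2 + (y0 + b)) * n1 + x0;
        acc += wyz * ((1.0 - fx) * vol[base] + fx * vol[base + 1]);
      }
    }
    out[m] = acc;
  }
  return out;
}

// Edge-preserving bilateral filter, cubic window of half-width `hw`.
// [[Rcpp::export]]
NumericVector cpp_bilateral3(NumericVector vol, IntegerVector dims, int hw,
                             double sigma_s, double sigma_r) {
  const int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  NumericVector out((R_xlen_t)n1 * n2 * n3);
  const double inv2ss = 1.0 / (2.0 * sigma_s * sigma_s);
  const double inv2sr = 1.0 / (2.0 * sigma_r * sigma_r);
  std::vector<double> sw((2 * hw + 1) * (2 * hw + 1) * (2 * hw + 1));
  int idx = 0;
  for (int c = -hw; c <= hw; ++c)
    for (int b = -hw; b <= hw; ++b)
      for (int a = -hw; a <= hw; ++a)
        sw[idx++] = std::exp(-(a * a + b * b + c * c) * inv2ss);
  for (int z = 0; z < n3; ++z)
    for (int y = 0; y < n2; ++y)
      for (int x = 0; x < n1; ++x) {
        const R_xlen_t i0 = (R_xlen_t)(z * n2 + y) * n1 + x;
        const double v0 = vol[i0];
        double num = 0.0, den = 0.0;
        int k = 0;
        for (int c = -hw; c <= hw; ++c) {
          int zz = z + c;
          if (zz < 0) zz = 0;
          if (zz > n3 - 1) zz = n3 - 1;
          for (int b = -hw; b <= hw; ++b) {
            int yy = y + b;
            if (yy < 0) yy = 0;
            if (yy > n2 - 1) yy = n2 - 1;
            const R_xlen_t base = (R_xlen_t)(zz * n2 + yy) * n1;
            for (int a = -hw; a <= hw; ++a, ++k) {
              int xx = x + a;
              if (xx < 0) xx = 0;
              if (xx > n1 - 1) xx = n1 - 1;
              const double v = vol[base + xx];
              const double d = v - v0;
              const double w = sw[k] * std::exp(-d * d * inv2sr);
              num += w * v;
              den += w;
            }
          }
        }
        out[i0] = num / den;
      }
  return out;
}

// 6-connected component labelling of a logical 3D mask.
// [[Rcpp::export]]
IntegerVector cpp_label3d(LogicalVector mask, IntegerVector dims) {
  const int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  const R_xlen_t n = (R_xlen_t)n1 * n2 * n3;
  IntegerVector lab(n, 0);
  int next = 0;
  std::queue<R_xlen_t> q;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (!mask[s] || lab[s]) continue;
    lab[s] = ++next;
    q.push(s);
    while (!q.empty()) {
      R_xlen_t i = q.front();
      q.pop();
      const int x = i % n1;
      const int y = (i / n1) % n2;
      const int z = i / ((R_xlen_t)n1 * n2);
      const int dx[6] = {1, -1, 0, 0, 0, 0};
      const int dy[6] = {0, 0, 1, -1, 0, 0};
      const int dz[6] = {0, 0, 0, 0, 1, -1};
      for (int d = 0; d < 6; ++d) {
        const int xx = x + dx[d], yy = y + dy[d], zz = z + dz[d];
        if (xx < 0 || xx >= n1 || yy < 0 || yy >= n2 || zz < 0 || zz >= n3)
          continue;
        const R_xlen_t j = (R_xlen_t)(zz * n2 + yy) * n1 + xx;
        if (mask[j] && !lab[j]) {
          lab[j] = next;
          q.push(j);
        }
      }
    }
  }
  return lab;
}
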