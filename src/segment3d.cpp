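#include <Rcpp.h>
#include <vector>
#include <queue>
#include <limits>
#include <cmath>

using namespace Rcpp;

// 3D connected-component labelling under 26-connectivity.
// mask is a logical array stored column-major with dims d (length 3).
// Labels are dense from 1, assigned in column-major scan order of the
// first voxel of each component.
// [[Rcpp::export]]
IntegerVector cpp_label3d(LogicalVector mask, IntegerVector d) {
  const int d0 = d[0], d1 = d[1], d2 = d[2];
  const R_xlen_t n = (R_xlen_t)d0 * d1 * d2;
  IntegerVector lab(n, 0);
  int next = 0;
  std::queue<R_xlen_t> q;
  for (R_xlen_t idx = 0; idx < n; ++idx) {
    if (!mask[idx] || lab[idx] != 0) continue;
    lab[idx] = ++next;
    q.push(idx);
    while (!q.empty()) {
      R_xlen_t cur = q.front(); q.pop();
      int i0 = (int)(cur % d0);
      int i1 = (int)((cur / d0) % d1);
      int i2 = (int)(cur / ((R_xlen_t)d0 * d1));
      for (int a = -1; a <= 1; ++a) {
        int j0 = i0 + a;
        if (j0 < 0 || j0 >= d0) continue;
        for (int b = -1; b <= 1; ++b) {
          int j1 = i1 + b;
          if (j1 < 0 || j1 >= d1) continue;
          for (int c = -1; c <= 1; ++c) {
            if (a == 0 && b == 0 && c == 0) continue;
            int j2 = i2 + c;
            if (j2 < 0 || j2 >= d2) continue;
            R_xlen_t nb = j0 + (R_xlen_t)d0 * (j1 + (R_xlen_t)d1 * j2);
            if (mask[nb] && lab[nb] == 0) {
              lab[nb] = next;
              q.push(nb);
            }
          }
        }
      }
    }
  }
  lab.attr("dim") = d;
  return lab;
}

// Felzenszwalb & Huttenlocher lower-envelope 1D squared distance transform,
// generalized to arbitrary sample values f and physical spacing s.
static void dt1d(std::vector<double> &f, std::vector<double> &dst,
                 std::vector<int> &v, std::vector<double> &z, double s) {
  const int n = (int)f.size();
  const double INF = std::numeric_limits<double>::infinity();
  const double s2 = s * s;
  int k = 0;
  v[0] = 0;
  z[0] = -INF;
  z[1] = INF;
  for (int q = 1; q < n; ++q) {
    if (f[q] == INF && f[v[k]] == INF) { // both empty: envelope unchanged
      continue;
    }
    double sq;
    while (true) {
      double fq = f[q], fv = f[v[k]];
      if (fv == INF) { // previous parabola at infinity: replace
        k--;
        if (k < 0) break;
        continue;
      }
      sq = ((fq + s2 * q * q) - (fv + s2 * v[k] * v[k])) / (2.0 * s2 * (q - v[k]));
      if (sq <= z[k]) {
        k--;
        if (k < 0) break;
      } else break;
    }
    if (k < 0) { k = 0; v[0] = q; z[0] = -INF; z[1] = INF; continue; }
    k++;
    v[k] = q;
    z[k] = sq;
    z[k + 1] = INF;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < (double)q) k++;
    double fv = f[v[k]];
    dst[q] = (fv == INF) ? INF : s2 * (q - v[k]) * (q - v[k]) + fv;
  }
}

// Anisotropy-aware Euclidean distance transform: physical distance of every
// voxel to the nearest TRUE voxel of mask (0 inside the mask). spacing gives
// the physical voxel size along each array dimension.
// [[Rcpp::export]]
NumericVector cpp_edt3d(LogicalVector mask, IntegerVector d, NumericVector spacing) {
  const int d0 = d[0], d1 = d[1], d2 = d[2];
  const R_xlen_t n = (R_xlen_t)d0 * d1 * d2;
  const double INF = std::numeric_limits<double>::infinity();
  std::vector<double> D(n);
  for (R_xlen_t i = 0; i < n; ++i) D[i] = mask[i] ? 0.0 : INF;

  int nmax = std::max(d0, std::max(d1, d2));
  std::vector<double> f(nmax), dst(nmax), z(nmax + 1);
  std::vector<int> v(nmax);

  // pass along dim 0
  for (int i2 = 0; i2 < d2; ++i2)
    for (int i1 = 0; i1 < d1; ++i1) {
      R_xlen_t base = (R_xlen_t)d0 * (i1 + (R_xlen_t)d1 * i2);
      f.resize(d0); dst.resize(d0);
      for (int i = 0; i < d0; ++i) f[i] = D[base + i];
      dt1d(f, dst, v, z, spacing[0]);
      for (int i = 0; i < d0; ++i) D[base + i] = dst[i];
    }
  // pass along dim 1
  for (int i2 = 0; i2 < d2; ++i2)
    for (int i0 = 0; i0 < d0; ++i0) {
      R_xlen_t base = i0 + (R_xlen_t)d0 * d1 * i2;
      f.resize(d1); dst.resize(d1);
      for (int i = 0; i < d1; ++i) f[i] = D[base + (R_xlen_t)d0 * i];
      dt1d(f, dst, v, z, spacing[1]);
      for (int i = 0; i < d1; ++i) D[base + (R_xlen_t)d0 * i] = dst[i];
    }
  // pass along dim 2
  const R_xlen_t s2stride = (R_xlen_t)d0 * d1;
  for (int i1 = 0; i1 < d1; ++i1)
    for (int i0 = 0; i0 < d0; ++i0) {
      R_xlen_t base = i0 + (R_xlen_t)d0 * i1;
      f.resize(d2); dst.resize(d2);
      for (int i = 0; i < d2; ++i) f[i] = D[base + s2stride * i];
      dt1d(f, dst, v, z, spacing[2]);
      for (int i = 0; i < d2; ++i) D[base + s2stride * i] = dst[i];
    }

  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i)
    out[i] = std::isinf(D[i]) ? R_PosInf : std::sqrt(D[i]);
  out.attr("dim") = d;
  return out;
}
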