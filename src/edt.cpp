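#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Exact squared Euclidean distance transform, separable lower-envelope
// algorithm (one parabola pass per axis).  INF is large enough that any
// in-grid squared distance (< 3 * 2048^2) stays exactly representable
// when an index square is added.
static const double DT_INF = 1e12;

static void dt1d(std::vector<double>& f, std::vector<double>& d,
                 std::vector<int>& v, std::vector<double>& z, int n) {
  int k = 0;
  v[0] = 0;
  z[0] = -DT_INF;
  z[1] = DT_INF;
  for (int q = 1; q < n; ++q) {
    double s = ((f[q] + (double)q * q) - (f[v[k]] + (double)v[k] * v[k])) /
               (2.0 * q - 2.0 * v[k]);
    while (s <= z[k]) {
      --k;
      s = ((f[q] + (double)q * q) - (f[v[k]] + (double)v[k] * v[k])) /
          (2.0 * q - 2.0 * v[k]);
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = DT_INF;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    double dq = (double)q - v[k];
    d[q] = dq * dq + f[v[k]];
  }
}

// Squared Euclidean distance from every voxel to the nearest TRUE voxel.
// Column-major 3-D layout, dims = (n1, n2, n3).  Voxels with no site in
// the grid get a value >= DT_INF.
// [[Rcpp::export]]
NumericVector cpp_sqdist(LogicalVector mask, IntegerVector dims) {
  const int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  const R_xlen_t n12 = (R_xlen_t)n1 * n2;
  const R_xlen_t n = n12 * n3;
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) out[i] = mask[i] ? 0.0 : DT_INF;

  const int nmax = std::max(n1, std::max(n2, n3));
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);

  // pass along axis 1 (stride 1)
  for (int k = 0; k < n3; ++k)
    for (int j = 0; j < n2; ++j) {
      const R_xlen_t base = (R_xlen_t)k * n12 + (R_xlen_t)j * n1;
      for (int i = 0; i < n1; ++i) f[i] = out[base + i];
      dt1d(f, d, v, z, n1);
      for (int i = 0; i < n1; ++i) out[base + i] = d[i];
    }
  // pass along axis 2 (stride n1)
  for (int k = 0; k < n3; ++k)
    for (int i = 0; i < n1; ++i) {
      const R_xlen_t base = (R_xlen_t)k * n12 + i;
      for (int j = 0; j < n2; ++j) f[j] = out[base + (R_xlen_t)j * n1];
      dt1d(f, d, v, z, n2);
      for (int j = 0; j < n2; ++j) out[base + (R_xlen_t)j * n1] = d[j];
    }
  // pass along axis 3 (stride n1*n2)
  for (int j = 0; j < n2; ++j)
    for (int i = 0; i < n1; ++i) {
      const R_xlen_t base = (R_xlen_t)j * n1 + i;
      for (int k = 0; k < n3; ++k) f[k] = out[base + (R_xlen_t)k * n12];
      dt1d(f, d, v, z, n3);
      for (int k = 0; k < n3; ++k) out[base + (R_xlen_t)k * n12] = d[k];
    }
  return out;
}
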