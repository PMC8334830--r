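#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static inline int clampi(int x, int lo, int hi) {
  return x < lo ? lo : (x > hi ? hi : x);
}

// Classic 3-D non-local means: every voxel is replaced by a weighted
// average of voxels in its search window, weights exp(-patchMSE / h^2).
// Borders handled by index clamping (edge replication).  Deterministic.
// [[Rcpp::export]]
NumericVector cpp_nlm(NumericVector img, IntegerVector dims, double h,
                      int patch, int search) {
  const int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  const R_xlen_t n12 = (R_xlen_t)n1 * n2;
  NumericVector out((R_xlen_t)n12 * n3);
  const double h2 = h * h;
  const int psz = 2 * patch + 1;
  const double np = (double)psz * psz * psz;

  for (int k = 0; k < n3; ++k)
    for (int j = 0; j < n2; ++j)
      for (int i = 0; i < n1; ++i) {
        double wsum = 0.0, vsum = 0.0;
        for (int ck = k - search; ck <= k + search; ++ck)
          for (int cj = j - search; cj <= j + search; ++cj)
            for (int ci = i - search; ci <= i + search; ++ci) {
              // mean squared patch difference
              double mse = 0.0;
              for (int pk = -patch; pk <= patch; ++pk)
                for (int pj = -patch; pj <= patch; ++pj)
                  for (int pi = -patch; pi <= patch; ++pi) {
                    const int a1 = clampi(i + pi, 0, n1 - 1);
                    const int a2 = clampi(j + pj, 0, n2 - 1);
                    const int a3 = clampi(k + pk, 0, n3 - 1);
                    const int b1 = clampi(ci + pi, 0, n1 - 1);
                    const int b2 = clampi(cj + pj, 0, n2 - 1);
                    const int b3 = clampi(ck + pk, 0, n3 - 1);
                    const double da =
                        img[(R_xlen_t)a3 * n12 + (R_xlen_t)a2 * n1 + a1] -
                        img[(R_xlen_t)b3 * n12 + (R_xlen_t)b2 * n1 + b1];
                    mse += da * da;
                  }
              mse /= np;
              const double w = std::exp(-mse / h2);
              const int c1 = clampi(ci, 0, n1 - 1);
              const int c2 = clampi(cj, 0, n2 - 1);
              const int c3 = clampi(ck, 0, n3 - 1);
              wsum += w;
              vsum += w * img[(R_xlen_t)c3 * n12 + (R_xlen_t)c2 * n1 + c1];
            }
        out[(R_xlen_t)k * n12 + (R_xlen_t)j * n1 + i] = vsum / wsum;
      }
  return out;
}
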