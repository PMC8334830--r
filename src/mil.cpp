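#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Mean-intercept-length sampling: for each unit direction, a family of
// parallel test lines covers the volume's bounding sphere; along each line
// we accumulate foreground length and count background->foreground
// crossings.  Returns per direction (foreground length, intercept count).
// dirs: ndir x 3 unit vectors (axis order matching dims); jitter: ndir x 2
// sub-spacing offsets of the line raster (from the caller's RNG).
// [[Rcpp::export]]
NumericMatrix cpp_mil(LogicalVector mask, IntegerVector dims,
                      NumericMatrix dirs, NumericMatrix jitter,
                      double spacing, double step) {
  const int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  const R_xlen_t n12 = (R_xlen_t)n1 * n2;
  const int ndir = dirs.nrow();
  NumericMatrix out(ndir, 2);

  const double c1 = n1 / 2.0, c2 = n2 / 2.0, c3 = n3 / 2.0;
  const double R = std::sqrt(c1 * c1 + c2 * c2 + c3 * c3);

  for (int d = 0; d < ndir; ++d) {
    const double u1 = dirs(d, 0), u2 = dirs(d, 1), u3 = dirs(d, 2);
    // orthonormal basis (a, b) perpendicular to u
    double a1, a2, a3;
    if (std::fabs(u1) < 0.9) { a1 = 1.0; a2 = 0.0; a3 = 0.0; }
    else                     { a1 = 0.0; a2 = 1.0; a3 = 0.0; }
    // a := normalize(a - (a.u)u)
    const double au = a1 * u1 + a2 * u2 + a3 * u3;
    a1 -= au * u1; a2 -= au * u2; a3 -= au * u3;
    const double an = std::sqrt(a1 * a1 + a2 * a2 + a3 * a3);
    a1 /= an; a2 /= an; a3 /= an;
    const double b1 = u2 * a3 - u3 * a2;
    const double b2 = u3 * a1 - u1 * a3;
    const double b3 = u1 * a2 - u2 * a1;

    double fglen = 0.0, ncross = 0.0;
    const double j1 = jitter(d, 0) * spacing, j2 = jitter(d, 1) * spacing;
    for (double s = -R + j1; s <= R; s += spacing)
      for (double t = -R + j2; t <= R; t += spacing) {
        bool prev_fg = false;
        int nfg = 0;
        for (double tau = -R; tau <= R; tau += step) {
          const double p1 = c1 + s * a1 + t * b1 + tau * u1;
          const double p2 = c2 + s * a2 + t * b2 + tau * u2;
          const double p3 = c3 + s * a3 + t * b3 + tau * u3;
          const int i1 = (int)std::floor(p1);
          const int i2 = (int)std::floor(p2);
          const int i3 = (int)std::floor(p3);
          bool fg = false;
          if (i1 >= 0 && i1 < n1 && i2 >= 0 && i2 < n2 && i3 >= 0 && i3 < n3)
            fg = mask[(R_xlen_t)i3 * n12 + (R_xlen_t)i2 * n1 + i1];
          if (fg) ++nfg;
          if (fg && !prev_fg) ncross += 1.0;
          prev_fg = fg;
        }
        fglen += nfg * step;
      }
    out(d, 0) = fglen;
    out(d, 1) = ncross;
  }
  return out;
}
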