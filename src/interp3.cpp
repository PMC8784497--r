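// Trilinear sampling of a 3D array (column-major, dims d1 x d2 x d3) at
// fractional 1-based voxel coordinates; out-of-grid points return `fill`.
// Degenerate axes (size 1) fall back to the single plane.
#include <Rcpp.h>
using namespace Rcpp;

// [[Rcpp::export]]
NumericVector interp3_linear_cpp(NumericVector arr, IntegerVector dims,
                                 NumericVector xi, NumericVector yi,
                                 NumericVector zi, double fill) {
  const int d1 = dims[0], d2 = dims[1], d3 = dims[2];
  const R_xlen_t n = xi.size();
  NumericVector out(n, fill);
  const double *a = arr.begin();
  const R_xlen_t sx = d1 > 1 ? 1 : 0;
  const R_xlen_t sy = d2 > 1 ? d1 : 0;
  const R_xlen_t sz = d3 > 1 ? (R_xlen_t)d1 * d2 : 0;
  for (R_xlen_t i = 0; i < n; ++i) {
    const double x = xi[i], y = yi[i], z = zi[i];
    if (!(x >= 1.0 && x <= d1 && y >= 1.0 && y <= d2 &&
          z >= 1.0 && z <= d3)) continue;
    double x0 = std::floor(x), y0 = std::floor(y), z0 = std::floor(z);
    if (x0 > d1 - 1) x0 = d1 - 1; if (x0 < 1) x0 = 1;
    if (y0 > d2 - 1) y0 = d2 - 1; if (y0 < 1) y0 = 1;
    if (z0 > d3 - 1) z0 = d3 - 1; if (z0 < 1) z0 = 1;
    double fx = x - x0, fy = y - y0, fz = z - z0;
    if (d1 == 1) { x0 = 1; fx = 0; }
    if (d2 == 1) { y0 = 1; fy = 0; }
    if (d3 == 1) { z0 = 1; fz = 0; }
    const R_xlen_t base = ((R_xlen_t)(z0 - 1) * d2 + (R_xlen_t)(y0 - 1)) * d1 +
      (R_xlen_t)x0 - 1;
    const double v000 = a[base],          v100 = a[base + sx];
    const double v010 = a[base + sy],     v110 = a[base + sx + sy];
    const double v001 = a[base + sz],     v101 = a[base + sx + sz];
    const double v011 = a[base + sy + sz], v111 = a[base + sx + sy + sz];
    const double c00 = v000 * (1 - fx) + v100 * fx;
    const double c10 = v010 * (1 - fx) + v110 * fx;
    const double c01 = v001 * (1 - fx) + v101 * fx;
    const double c11 = v011 * (1 - fx) + v111 * fx;
    const double c0 = c00 * (1 - fy) + c10 * fy;
    const double c1 = c01 * (1 - fy) + c11 * fy;
    out[i] = c0 * (1 - fz) + c1 * fz;
  }
  return out;
}
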