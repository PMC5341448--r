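#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Analytic eigenvalues of a symmetric 3x3 matrix (trigonometric method).
// Inputs are the six unique Hessian components per voxel; output columns are
// the eigenvalues sorted by increasing magnitude, as vesselness requires.
// [[Rcpp::export]]
NumericMatrix sym3_eigenvalues(NumericVector a11, NumericVector a22,
                               NumericVector a33, NumericVector a12,
                               NumericVector a13, NumericVector a23) {
  const R_xlen_t n = a11.size();
  if (a22.size() != n || a33.size() != n || a12.size() != n ||
      a13.size() != n || a23.size() != n)
    stop("Hessian component vectors must have equal length");
  NumericMatrix out(n, 3);
  const double twopi3 = 2.0 * M_PI / 3.0;
  for (R_xlen_t i = 0; i < n; ++i) {
    const double h11 = a11[i], h22 = a22[i], h33 = a33[i];
    const double h12 = a12[i], h13 = a13[i], h23 = a23[i];
    double e1, e2, e3;
    const double p1 = h12 * h12 + h13 * h13 + h23 * h23;
    if (p1 == 0.0) {
      e1 = h11; e2 = h22; e3 = h33;
    } else {
      const double q = (h11 + h22 + h33) / 3.0;
      const double b11 = h11 - q, b22 = h22 - q, b33 = h33 - q;
      const double p2 = b11 * b11 + b22 * b22 + b33 * b33 + 2.0 * p1;
      const double p = std::sqrt(p2 / 6.0);
      // det(B)/2 for B = (A - qI)/p
      const double c11 = b11 / p, c22 = b22 / p, c33 = b33 / p;
      const double c12 = h12 / p, c13 = h13 / p, c23 = h23 / p;
      double r = (c11 * (c22 * c33 - c23 * c23) -
                  c12 * (c12 * c33 - c23 * c13) +
                  c13 * (c12 * c23 - c22 * c13)) / 2.0;
      if (r < -1.0) r = -1.0;
      if (r > 1.0) r = 1.0;
      const double phi = std::acos(r) / 3.0;
      e1 = q + 2.0 * p * std::cos(phi);            // largest
      e3 = q + 2.0 * p * std::cos(phi + twopi3);   // smallest
      e2 = 3.0 * q - e1 - e3;
    }
    // sort by |lambda| ascending
    double v[3] = {e1, e2, e3};
    for (int a = 0; a < 2; ++a)
      for (int b = 0; b < 2 - a; ++b)
        if (std::fabs(v[b]) > std::fabs(v[b + 1])) {
          const double t = v[b]; v[b] = v[b + 1]; v[b + 1] = t;
        }
    out(i, 0) = v[0]; out(i, 1) = v[1]; out(i, 2) = v[2];
  }
  return out;
}
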