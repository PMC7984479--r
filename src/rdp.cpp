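// Relative difference penalty and its gradient.
//
// R(x) = sum_j sum_{k in N_j} w_jk (x_j - x_k)^2 /
//                               (x_j + x_k + gamma |x_j - x_k|)
// over ordered neighbor pairs; pairs with zero denominator contribute 0
// (removable singularity at x_j = x_k = 0).  The C++ loop walks each
// unordered pair once and doubles it.

#include <Rcpp.h>
using namespace Rcpp;

static inline double pair_value(double a, double b, double gamma) {
  double d = a - b;
  double s = a + b + gamma * std::fabs(d);
  if (s <= 0.0) return 0.0;
  return d * d / s;
}

// d/da of pair_value(a, b)
static inline double pair_deriv(double a, double b, double gamma) {
  double d = a - b;
  double s = a + b + gamma * std::fabs(d);
  if (s <= 0.0) return 0.0;
  double sgn = (d > 0.0) - (d < 0.0);
  return (2.0 * d * s - d * d * (1.0 + gamma * sgn)) / (s * s);
}

// offsets: m x 3 integer matrix of half-set neighbor offsets
// weights: length-m nonnegative weights w_jk
// [[Rcpp::export(name = ".rdp_value_cpp")]]
double rdp_value_cpp(NumericVector x, IntegerVector dim,
                     IntegerMatrix offsets, NumericVector weights,
                     double gamma) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  double total = 0.0;
  for (int m = 0; m < offsets.nrow(); ++m) {
    const int ox = offsets(m, 0), oy = offsets(m, 1), oz = offsets(m, 2);
    const double w = weights[m];
    for (int k = std::max(0, -oz); k < nz - std::max(0, oz); ++k) {
      for (int j = std::max(0, -oy); j < ny - std::max(0, oy); ++j) {
        const R_xlen_t base = (R_xlen_t)(k) * nx * ny + (R_xlen_t)(j) * nx;
        const R_xlen_t nb = (R_xlen_t)(k + oz) * nx * ny +
                            (R_xlen_t)(j + oy) * nx + ox;
        for (int i = std::max(0, -ox); i < nx - std::max(0, ox); ++i) {
          total += 2.0 * w * pair_value(x[base + i], x[nb + i], gamma);
        }
      }
    }
  }
  return total;
}

// [[Rcpp::export(name = ".rdp_gradient_cpp")]]
NumericVector rdp_gradient_cpp(NumericVector x, IntegerVector dim,
                               IntegerMatrix offsets, NumericVector weights,
                               double gamma) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  NumericVector g(x.size());
  for (int m = 0; m < offsets.nrow(); ++m) {
    const int ox = offsets(m, 0), oy = offsets(m, 1), oz = offsets(m, 2);
    const double w = weights[m];
    for (int k = std::max(0, -oz); k < nz - std::max(0, oz); ++k) {
      for (int j = std::max(0, -oy); j < ny - std::max(0, oy); ++j) {
        const R_xlen_t base = (R_xlen_t)(k) * nx * ny + (R_xlen_t)(j) * nx;
        const R_xlen_t nb = (R_xlen_t)(k + oz) * nx * ny +
                            (R_xlen_t)(j + oy) * nx + ox;
        for (int i = std::max(0, -ox); i < nx - std::max(0, ox); ++i) {
          const double a = x[base + i], b = x[nb + i];
          g[base + i] += 2.0 * w * pair_deriv(a, b, gamma);
          g[nb + i]   += 2.0 * w * pair_deriv(b, a, gamma);
        }
      }
    }
  }
  return g;
}
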