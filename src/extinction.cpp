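#include <Rcpp.h>
using namespace Rcpp;

// Stage encoding shared with R: type 0 = Poisson growth (param = mean),
// type 1 = binomial sampling (param = survival probability).
// Stages are stored in time order; a lineage PGF is the composition with the
// first stage outermost, so evaluation applies stages in reverse time order.

inline double apply_stages(double x, const IntegerVector& type,
                           const NumericVector& param) {
  for (int i = type.size() - 1; i >= 0; --i) {
    if (type[i] == 0) {
      x = std::exp(param[i] * (x - 1.0));
    } else {
      x = 1.0 - param[i] + param[i] * x;
    }
  }
  return x;
}

// Fixed-point iteration x <- phi(x) from x = 0 for a single composite cycle.
// [[Rcpp::export]]
List cpp_fixed_point(IntegerVector type, NumericVector param, double tol,
                     int max_iter) {
  double x = 0.0;
  bool converged = false;
  int it = 0;
  while (it < max_iter) {
    double xn = apply_stages(x, type, param);
    ++it;
    if (std::fabs(xn - x) < tol) {
      x = xn;
      converged = true;
      break;
    }
    x = xn;
  }
  return List::create(_["q"] = x, _["iterations"] = it,
                      _["converged"] = converged);
}

// Backward accumulation for the time-inhomogeneous extinction recursion:
// q = phi_0(phi_1(...phi_n(x0))). All stages of all cycles are passed flat in
// time order; evaluation runs once through them in reverse.
// [[Rcpp::export]]
double cpp_nested_stages(IntegerVector type, NumericVector param, double x0) {
  return apply_stages(x0, type, param);
}

// Cubic-polynomial offspring PGFs f(x) = a + b x + c x^2 + d x^3, one row per
// generation in time order (first generation outermost).
// [[Rcpp::export]]
double cpp_nested_poly(NumericMatrix coef, double x0) {
  double x = x0;
  for (int k = coef.nrow() - 1; k >= 0; --k) {
    x = coef(k, 0) + x * (coef(k, 1) + x * (coef(k, 2) + x * coef(k, 3)));
  }
  return x;
}

// [[Rcpp::export]]
List cpp_fixed_point_poly(double a, double b, double c, double d, double tol,
                          int max_iter) {
  double x = 0.0;
  bool converged = false;
  int it = 0;
  while (it < max_iter) {
    double xn = a + x * (b + x * (c + x * d));
    ++it;
    if (std::fabs(xn - x) < tol) {
      x = xn;
      converged = true;
      break;
    }
    x = xn;
  }
  return List::create(_["q"] = x, _["iterations"] = it,
                      _["converged"] = converged);
}
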