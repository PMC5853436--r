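#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Gravitropic correlated random walk: heading is pulled toward the
// downward vertical with weight w each step, then perturbed by the
// pre-drawn noise increments eps (radians). Returns the (n+1) x 2 path.
// [[Rcpp::export]]
NumericMatrix grow_curve_cpp(NumericVector start, double init_angle,
                             NumericVector lens, double w,
                             NumericVector eps) {
  const int n = lens.size();
  NumericMatrix out(n + 1, 2);
  out(0, 0) = start[0];
  out(0, 1) = start[1];
  double cur = init_angle, x = start[0], y = start[1];
  for (int t = 0; t < n; ++t) {
    cur = std::atan2((1.0 - w) * std::sin(cur),
                     (1.0 - w) * std::cos(cur) + w) + eps[t];
    x += std::sin(cur) * lens[t];
    y += std::cos(cur) * lens[t];
    out(t + 1, 0) = x;
    out(t + 1, 1) = y;
  }
  return out;
}
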