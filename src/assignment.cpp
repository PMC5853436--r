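#include <Rcpp.h>
#include <vector>
#include <limits>
#include <cmath>
using namespace Rcpp;

static double hungarian_total(const std::vector<double>& a, int n) {
  // square cost matrix a (row-major, n x n); returns minimal total cost
  const double INF = std::numeric_limits<double>::infinity();
  std::vector<double> u(n + 1, 0.0), v(n + 1, 0.0);
  std::vector<int> p(n + 1, 0), way(n + 1, 0);
  for (int i = 1; i <= n; ++i) {
    p[0] = i;
    int j0 = 0;
    std::vector<double> minv(n + 1, INF);
    std::vector<char> used(n + 1, 0);
    do {
      used[j0] = 1;
      int i0 = p[j0], j1 = -1;
      double delta = INF;
      const double* row = &a[(i0 - 1) * n];
      for (int j = 1; j <= n; ++j) {
        if (!used[j]) {
          double cur = row[j - 1] - u[i0] - v[j];
          if (cur < minv[j]) { minv[j] = cur; way[j] = j0; }
          if (minv[j] < delta) { delta = minv[j]; j1 = j; }
        }
      }
      for (int j = 0; j <= n; ++j) {
        if (used[j]) { u[p[j]] += delta; v[j] -= delta; }
        else { minv[j] -= delta; }
      }
      j0 = j1;
    } while (p[j0] != 0);
    do { int j1 = way[j0]; p[j0] = p[j1]; j0 = j1; } while (j0);
  }
  double total = 0.0;
  for (int j = 1; j <= n; ++j)
    if (p[j] > 0) total += a[(p[j] - 1) * n + (j - 1)];
  return total;
}

// Minimum-cost matching between two flattened curve sets (rows = curves,
// 2m columns = x then y samples). Curves unmatched because of a count
// difference pay their RMS distance to the origin (the degenerate curve).
// [[Rcpp::export]]
double curve_set_cost_cpp(NumericMatrix A, NumericMatrix B, int m) {
  const int na = A.nrow(), nb = B.nrow();
  if (na == 0 && nb == 0) return 0.0;
  std::vector<double> sa(na), sb(nb);
  for (int i = 0; i < na; ++i) {
    double s = 0.0;
    for (int k = 0; k < A.ncol(); ++k) s += A(i, k) * A(i, k);
    sa[i] = s;
  }
  for (int j = 0; j < nb; ++j) {
    double s = 0.0;
    for (int k = 0; k < B.ncol(); ++k) s += B(j, k) * B(j, k);
    sb[j] = s;
  }
  if (na == 0) {
    double t = 0.0;
    for (int j = 0; j < nb; ++j) t += std::sqrt(sb[j] / m);
    return t;
  }
  if (nb == 0) {
    double t = 0.0;
    for (int i = 0; i < na; ++i) t += std::sqrt(sa[i] / m);
    return t;
  }
  const int n = na > nb ? na : nb;
  std::vector<double> cost(n * n, 0.0);
  const int twom = A.ncol();
  for (int i = 0; i < na; ++i) {
    for (int j = 0; j < nb; ++j) {
      double dot = 0.0;
      for (int k = 0; k < twom; ++k) dot += A(i, k) * B(j, k);
      double d2 = sa[i] + sb[j] - 2.0 * dot;
      cost[i * n + j] = std::sqrt((d2 > 0.0 ? d2 : 0.0) / m);
    }
  }
  if (na < nb) {
    for (int i = na; i < n; ++i)          // dummy rows: B curve unmatched
      for (int j = 0; j < nb; ++j) cost[i * n + j] = std::sqrt(sb[j] / m);
  } else if (nb < na) {
    for (int i = 0; i < na; ++i)          // dummy columns: A curve unmatched
      for (int j = nb; j < n; ++j) cost[i * n + j] = std::sqrt(sa[i] / m);
  }
  return hungarian_total(cost, n);
}

// Hungarian algorithm with potentials (shortest augmenting path), O(n^2 m).
// Requires nrow <= ncol; returns, for each row, the 1-based column assigned.
// [[Rcpp::export]]
IntegerVector solve_assignment_cpp(NumericMatrix a) {
  const int n = a.nrow(), m = a.ncol();
  if (n == 0) return IntegerVector(0);
  if (n > m) stop("cost matrix must have nrow <= ncol");
  const double INF = std::numeric_limits<double>::infinity();
  std::vector<double> u(n + 1, 0.0), v(m + 1, 0.0);
  std::vector<int> p(m + 1, 0), way(m + 1, 0);
  for (int i = 1; i <= n; ++i) {
    p[0] = i;
    int j0 = 0;
    std::vector<double> minv(m + 1, INF);
    std::vector<char> used(m + 1, 0);
    do {
      used[j0] = 1;
      int i0 = p[j0], j1 = -1;
      double delta = INF;
      for (int j = 1; j <= m; ++j) {
        if (!used[j]) {
          double cur = a(i0 - 1, j - 1) - u[i0] - v[j];
          if (cur < minv[j]) { minv[j] = cur; way[j] = j0; }
          if (minv[j] < delta) { delta = minv[j]; j1 = j; }
        }
      }
      for (int j = 0; j <= m; ++j) {
        if (used[j]) { u[p[j]] += delta; v[j] -= delta; }
        else { minv[j] -= delta; }
      }
      j0 = j1;
    } while (p[j0] != 0);
    do { int j1 = way[j0]; p[j0] = p[j1]; j0 = j1; } while (j0);
  }
  IntegerVector ans(n);
  for (int j = 1; j <= m; ++j)
    if (p[j] > 0) ans[p[j] - 1] = j;
  return ans;
}
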