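#include <Rcpp.h>
using namespace Rcpp;

// Poisson-binomial mass and tail probabilities by direct dynamic-programming
// convolution: fold in one Bernoulli trial at a time. Exact in double
// precision (no characteristic-function or saddlepoint approximation).

static void check_probs(const NumericVector& p) {
  for (R_xlen_t i = 0; i < p.size(); ++i) {
    if (NumericVector::is_na(p[i]) || p[i] < 0.0 || p[i] > 1.0)
      stop("success probabilities must lie in [0, 1]");
  }
}

// [[Rcpp::export(name = ".poibin_pmf_cpp")]]
NumericVector poibin_pmf_cpp(NumericVector p) {
  check_probs(p);
  R_xlen_t n = p.size();
  NumericVector f(n + 1);
  f[0] = 1.0;
  for (R_xlen_t i = 0; i < n; ++i) {
    double pi = p[i], qi = 1.0 - pi;
    // iterate downwards so f[k-1] is still the previous-stage value
    for (R_xlen_t k = i + 1; k >= 1; --k)
      f[k] = f[k] * qi + f[k - 1] * pi;
    f[0] *= qi;
  }
  return f;
}

// P(X <= k) via a DP truncated at k+1 live states plus one absorbing
// ">k" state; O(n * k) instead of O(n^2).
// [[Rcpp::export(name = ".poibin_lower_cpp")]]
double poibin_lower_cpp(NumericVector p, int k) {
  check_probs(p);
  R_xlen_t n = p.size();
  if (k < 0) return 0.0;
  if (k >= n) return 1.0;
  std::vector<double> f(k + 1, 0.0);
  f[0] = 1.0;
  double absorbed = 0.0; // mass at counts > k
  for (R_xlen_t i = 0; i < n; ++i) {
    double pi = p[i], qi = 1.0 - pi;
    absorbed = absorbed + f[k] * pi;
    for (int s = k; s >= 1; --s)
      f[s] = f[s] * qi + f[s - 1] * pi;
    f[0] *= qi;
  }
  double tot = 0.0;
  for (int s = 0; s <= k; ++s) tot += f[s];
  // guard against roundoff
  if (tot < 0.0) tot = 0.0;
  if (tot > 1.0) tot = 1.0;
  return tot;
}

// P(X >= k). For k near n, computed on the complementary count
// (n - X ~ Poisson-binomial(1 - p)) so that small tails keep full
// relative precision; otherwise as 1 - P(X <= k - 1).
// [[Rcpp::export(name = ".poibin_upper_cpp")]]
double poibin_upper_cpp(NumericVector p, int k) {
  check_probs(p);
  R_xlen_t n = p.size();
  if (k <= 0) return 1.0;
  if (k > n) return 0.0;
  if ((n - k) < (k - 1)) {
    NumericVector q(n);
    for (R_xlen_t i = 0; i < n; ++i) q[i] = 1.0 - p[i];
    return poibin_lower_cpp(q, (int)(n - k));
  }
  double lo = poibin_lower_cpp(p, k - 1);
  double res = 1.0 - lo;
  if (res < 0.0) res = 0.0;
  return res;
}

// Per-tumor event probabilities for the group statistics, computed in one
// pass over a |I| x m probability submatrix (rows = genes in the group).
// statistic: 0 = coverage, 1 = exclusivity, 2 = impurity.
// [[Rcpp::export(name = ".group_probs_cpp")]]
NumericVector group_probs_cpp(NumericMatrix pm, int statistic) {
  int g = pm.nrow(), m = pm.ncol();
  NumericVector out(m);
  for (int j = 0; j < m; ++j) {
    double none = 1.0;   // P(no gene altered)
    double exactly1 = 0.0;
    for (int i = 0; i < g; ++i) {
      double pij = pm(i, j);
      exactly1 = exactly1 * (1.0 - pij) + none * pij;
      none *= (1.0 - pij);
    }
    double val;
    if (statistic == 0) val = 1.0 - none;
    else if (statistic == 1) val = exactly1;
    else val = 1.0 - none - exactly1;
    if (val < 0.0) val = 0.0;
    if (val > 1.0) val = 1.0;
    out[j] = val;
  }
  return out;
}
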