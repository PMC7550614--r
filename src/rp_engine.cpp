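#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <numeric>
#include <vector>
using namespace Rcpp;

// Rank-product core for one two-class labelling.
//
// For each case-control pairing (rows of `pairs`, 1-based indices into
// case_idx / control_idx), per-gene log2 differences are ranked with rank 1 =
// most upregulated (average ranks on ties); with average ties the
// down-ranking satisfies r_down = n + 1 - r_up, so one sort per pairing
// yields both directions. Returns the geometric mean of ranks per gene under
// each ordering.
//
// [[Rcpp::export]]
List rp_engine(NumericMatrix values, IntegerVector case_idx,
               IntegerVector control_idx, IntegerMatrix pairs) {
  const int n = values.nrow();
  const int K = pairs.nrow();
  if (K == 0) stop("no pairings supplied");
  std::vector<double> d(n), rk(n);
  std::vector<int> ord(n);
  std::vector<double> lr_up(n, 0.0), lr_dn(n, 0.0);
  // average-tie ranks are half-integers in [1, n]; precompute log(k/2)
  std::vector<double> log_half(2 * n + 1);
  for (int k = 1; k <= 2 * n; ++k) log_half[k] = std::log(k / 2.0);

  for (int k = 0; k < K; ++k) {
    const int ci = case_idx[pairs(k, 0) - 1] - 1;
    const int li = control_idx[pairs(k, 1) - 1] - 1;
    const double* vc = &values(0, ci);
    const double* vl = &values(0, li);
    for (int i = 0; i < n; ++i) d[i] = vc[i] - vl[i];
    std::iota(ord.begin(), ord.end(), 0);
    std::sort(ord.begin(), ord.end(),
              [&](int a, int b) { return d[a] > d[b]; });
    int i = 0;
    while (i < n) {
      int j = i;
      while (j + 1 < n && d[ord[j + 1]] == d[ord[i]]) ++j;
      const double avg = (i + j) / 2.0 + 1.0;  // average rank for the tie run
      for (int t = i; t <= j; ++t) rk[ord[t]] = avg;
      i = j + 1;
    }
    for (int g = 0; g < n; ++g) {
      const int two_r = (int)(2.0 * rk[g] + 0.5);
      lr_up[g] += log_half[two_r];
      lr_dn[g] += log_half[2 * (n + 1) - two_r];
    }
  }
  NumericVector rp_up(n), rp_dn(n);
  for (int g = 0; g < n; ++g) {
    rp_up[g] = std::exp(lr_up[g] / K);
    rp_dn[g] = std::exp(lr_dn[g] / K);
  }
  return List::create(_["rp_up"] = rp_up, _["rp_down"] = rp_dn);
}
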