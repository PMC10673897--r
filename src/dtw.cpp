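#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>

using namespace Rcpp;

// Classic DTW dynamic program, O(min(n,m)) memory.
// cost_type: 0 = squared difference, 1 = absolute difference.
// window: Sakoe-Chiba band half-width in days; <= 0 means unconstrained.
// A window narrower than |n - m| leaves no feasible path -> +Inf, the R
// wrapper turns that into an error.
static double dtw_core(const double* a, const int n, const double* b,
                       const int m, const int cost_type, const int window,
                       const bool final_sqrt) {
  const double INF = R_PosInf;
  std::vector<double> prev(m + 1, INF), cur(m + 1, INF);
  prev[0] = 0.0;
  for (int i = 1; i <= n; ++i) {
    std::fill(cur.begin(), cur.end(), INF);
    int jlo = 1, jhi = m;
    if (window > 0) {
      jlo = std::max(1, i - window);
      jhi = std::min(m, i + window);
    }
    for (int j = jlo; j <= jhi; ++j) {
      const double d = a[i - 1] - b[j - 1];
      const double cost = (cost_type == 0) ? d * d : std::fabs(d);
      const double best = std::min(prev[j], std::min(cur[j - 1], prev[j - 1]));
      if (best == INF) continue;
      cur[j] = cost + best;
    }
    std::swap(prev, cur);
  }
  double out = prev[m];
  if (final_sqrt && cost_type == 0 && R_FINITE(out)) out = std::sqrt(out);
  return out;
}

// [[Rcpp::export]]
double dtw_dist_cpp(NumericVector a, NumericVector b, int cost_type,
                    int window, bool final_sqrt) {
  return dtw_core(a.begin(), a.size(), b.begin(), b.size(), cost_type, window,
                  final_sqrt);
}

// [[Rcpp::export]]
NumericMatrix dtw_pairwise_cpp(List series, int cost_type, int window,
                               bool final_sqrt) {
  const int n = series.size();
  std::vector<NumericVector> xs(n);
  for (int i = 0; i < n; ++i) xs[i] = as<NumericVector>(series[i]);
  NumericMatrix out(n, n);
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      const double d = dtw_core(xs[i].begin(), xs[i].size(), xs[j].begin(),
                                xs[j].size(), cost_type, window, final_sqrt);
      out(i, j) = d;
      out(j, i) = d;
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix dtw_cross_cpp(List xs, List ys, int cost_type, int window,
                            bool final_sqrt) {
  const int n = xs.size(), m = ys.size();
  std::vector<NumericVector> as_(n), bs(m);
  for (int i = 0; i < n; ++i) as_[i] = as<NumericVector>(xs[i]);
  for (int j = 0; j < m; ++j) bs[j] = as<NumericVector>(ys[j]);
  NumericMatrix out(n, m);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < m; ++j)
      out(i, j) = dtw_core(as_[i].begin(), as_[i].size(), bs[j].begin(),
                           bs[j].size(), cost_type, window, final_sqrt);
  return out;
}
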