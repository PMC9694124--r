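#include <Rcpp.h>
#include <R_ext/Random.h>
using namespace Rcpp;

// Monte Carlo without-replacement resampling kernel for a two-sample
// permutation test on pooled binary item outcomes.
//
// Each iteration draws a pseudo-"b" of size nb from the pooled vector by a
// partial Fisher-Yates shuffle (R's RNG via R_unif_index, so results are
// reproducible from set.seed in R) and counts the draw as extreme under the
// inclusive rule. Because the data are binary, the permuted mean difference
// 100*(k/nb - (K-k)/na) is a strictly increasing function of k, the number
// of successes assigned to pseudo-"b"; extremity is therefore decided in
// exact integer arithmetic on k, never on floating-point differences:
//   one-sided (greater):  k >= kb_obs
//   two-sided:            |k*n - K*nb| >= |kb_obs*n - K*nb|
// where n = na + nb and K is the pooled success count.
//
// [[Rcpp::export]]
double mc_extreme_count(IntegerVector pooled, int nb, int n_resamples,
                        int kb_obs, bool two_sided) {
  const int n = pooled.size();
  if (nb <= 0 || nb >= n)
    stop("pseudo-'b' size must satisfy 0 < nb < pooled length");
  std::vector<int> v(pooled.begin(), pooled.end());
  long long K = 0;
  for (int i = 0; i < n; ++i) K += v[i];
  const long long obs = (long long)kb_obs * n - K * (long long)nb;
  const long long obs_abs = obs >= 0 ? obs : -obs;

  double extreme = 0.0;
  for (int r = 0; r < n_resamples; ++r) {
    long long k = 0;
    for (int i = 0; i < nb; ++i) {
      int j = i + (int) R_unif_index((double)(n - i));
      std::swap(v[i], v[j]);
      k += v[i];
    }
    if (two_sided) {
      long long s = k * (long long)n - K * (long long)nb;
      if ((s >= 0 ? s : -s) >= obs_abs) extreme += 1.0;
    } else {
      if (k >= kb_obs) extreme += 1.0;
    }
  }
  return extreme;
}
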