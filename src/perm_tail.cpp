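#include <Rcpp.h>
#include <vector>

// Monte-Carlo tail of the rank-sum null: each replicate draws k distinct
// ranks from {1..n} by a partial Fisher-Yates shuffle driven by R's RNG
// (so results are reproducible under set.seed). Returns the number of
// replicates whose rank sum is <= observed.
// [[Rcpp::export]]
double perm_tail_hits(int n, int k, double observed, double n_perm) {
  std::vector<int> idx(n);
  for (int i = 0; i < n; ++i) idx[i] = i + 1;
  const long long B = (long long) n_perm;
  double hits = 0.0;
  for (long long b = 0; b < B; ++b) {
    long long sum = 0;
    for (int j = 0; j < k; ++j) {
      int r = j + (int) (unif_rand() * (n - j));
      if (r >= n) r = n - 1; // guard against unif_rand() == 1
      std::swap(idx[j], idx[r]);
      sum += idx[j];
    }
    if ((double) sum <= observed) hits += 1.0;
  }
  return hits;
}
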