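#include <Rcpp.h>
#include <algorithm>
#include <vector>

using namespace Rcpp;

// Count how many of n_perm uniformly drawn k-subsets of {1..n} have a
// running-sum KS score >= threshold. Uses R's RNG (caller seeds it), with
// Floyd-style partial sampling so each draw costs O(k log k), not O(n).
// The running sum peaks right after a hit, so for sorted positions p the
// score is max(0, max_i(i/k - (p_i - i)/(n - k))).
// [[Rcpp::export(name = ".ks_perm_count_ge")]]
int ks_perm_count_ge(int n, int k, double threshold, int n_perm) {
  std::vector<int> stamp(n + 1, -1);
  std::vector<double> pos(k);
  const double invk = 1.0 / k, invnk = 1.0 / (n - k);
  int count = 0;
  for (int b = 0; b < n_perm; ++b) {
    // Floyd's algorithm: j runs over the last k pool sizes
    int filled = 0;
    for (int j = n - k; j < n; ++j) {
      int t = 1 + (int)(unif_rand() * (j + 1));
      if (t > j + 1) t = j + 1;  // guard against unif_rand() == 1.0
      if (stamp[t] == b) t = j + 1;
      stamp[t] = b;
      pos[filled++] = t;
    }
    std::sort(pos.begin(), pos.end());
    double best = 0.0;
    for (int i = 0; i < k; ++i) {
      double dev = (i + 1) * invk - (pos[i] - (i + 1)) * invnk;
      if (dev > best) best = dev;
    }
    if (best >= threshold) ++count;
  }
  return count;
}
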