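#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Enrichment score of a hit-position pattern against a ranked list, given
// the per-position hit weights |score|^p in rank order. Positions are
// 0-based and must be sorted ascending. Exact-magnitude ties between the
// positive and negative extremum resolve to the positive branch.
static double es_from_positions(const std::vector<int>& pos,
                                const NumericVector& absw,
                                int n_total) {
  const int k = (int)pos.size();
  const double miss = 1.0 / (double)(n_total - k);
  double sw = 0.0;
  for (int i = 0; i < k; ++i) sw += absw[pos[i]];
  double cum = 0.0, maxpos = 0.0, minneg = 0.0;
  for (int i = 0; i < k; ++i) {
    const double gap = (double)(pos[i] - i) * miss;
    const double before = cum - gap;
    if (before < minneg) minneg = before;
    cum += (sw > 0.0) ? absw[pos[i]] / sw : 1.0 / (double)k;
    const double at = cum - gap;
    if (at > maxpos) maxpos = at;
  }
  // positive branch wins magnitude ties (tolerance guards rounding noise)
  const double tol = 1e-12 * std::max(maxpos, -minneg);
  return (maxpos >= -minneg - tol) ? maxpos : minneg;
}

// Sample `nperm` gene sets of size `k` uniformly without replacement from a
// universe of size n = absw.size() (using R's RNG, so results are
// reproducible under set.seed) and return their enrichment scores.
// [[Rcpp::export(name = ".null_es_batch")]]
NumericVector null_es_batch(NumericVector absw, int k, int nperm) {
  const int n = absw.size();
  if (k < 1 || k >= n) stop("set size must satisfy 1 <= k < universe size");
  std::vector<int> pool(n);
  for (int i = 0; i < n; ++i) pool[i] = i;
  std::vector<int> pos(k);
  NumericVector out(nperm);
  for (int b = 0; b < nperm; ++b) {
    // partial Fisher-Yates: first k entries of pool become the draw
    for (int i = 0; i < k; ++i) {
      int j = i + (int)(unif_rand() * (double)(n - i));
      if (j >= n) j = n - 1;
      std::swap(pool[i], pool[j]);
      pos[i] = pool[i];
    }
    std::sort(pos.begin(), pos.end());
    out[b] = es_from_positions(pos, absw, n);
  }
  return out;
}
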