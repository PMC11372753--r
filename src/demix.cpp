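#include <Rcpp.h>
using namespace Rcpp;

// Label-swap Metropolis Monte Carlo on a fixed neighbour graph.
// Energy: -J per same-label neighbour pair (kT units). A move picks two
// sites uniformly and exchanges their labels; accepted with prob
// min(1, exp(-dE)). Uses R's RNG so the caller's seed governs everything.
//
// labels: 0-based integer species labels, one per packed site
// nbr_flat / nbr_off: CSR neighbour lists (0-based packed indices)
// [[Rcpp::export]]
IntegerVector demix_mc(IntegerVector labels, IntegerVector nbr_flat,
                       IntegerVector nbr_off, double J, double n_attempts) {
  int n = labels.size();
  IntegerVector lab = clone(labels);
  if (n < 2 || J < 0.0) return lab;
  RNGScope scope;
  for (double t = 0; t < n_attempts; t += 1.0) {
    int i = (int)(unif_rand() * n); if (i == n) i = n - 1;
    int j = (int)(unif_rand() * n); if (j == n) j = n - 1;
    if (lab[i] == lab[j]) continue;
    // same-label bond count change if i and j swap labels
    int li = lab[i], lj = lab[j];
    int before = 0, after = 0;
    for (int k = nbr_off[i]; k < nbr_off[i + 1]; ++k) {
      int m = nbr_flat[k];
      if (m == j) continue;            // i-j bond unchanged by a swap
      if (lab[m] == li) ++before;
      if (lab[m] == lj) ++after;
    }
    for (int k = nbr_off[j]; k < nbr_off[j + 1]; ++k) {
      int m = nbr_flat[k];
      if (m == i) continue;
      if (lab[m] == lj) ++before;
      if (lab[m] == li) ++after;
    }
    double dE = -J * (after - before);
    if (dE <= 0.0 || unif_rand() < std::exp(-dE)) {
      lab[i] = lj;
      lab[j] = li;
    }
  }
  return lab;
}
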