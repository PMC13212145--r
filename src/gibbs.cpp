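#include <Rcpp.h>
using namespace Rcpp;

// Single-chain Gibbs sampler for a binary (0/1) Ising model
//   P(x) propto exp(sum_i tau_i x_i + sum_{i<j} beta_ij x_i x_j).
// Systematic node-update order; returns kept states after burn-in with the
// given thinning interval.  Uses R's RNG so set.seed() governs the draws.
// [[Rcpp::export(name = ".gibbs_ising")]]
IntegerMatrix gibbs_ising(NumericVector tau, NumericMatrix beta,
                          int n_keep, int burn_in, int thin,
                          IntegerVector init) {
  int p = tau.size();
  std::vector<int> x(p);
  for (int i = 0; i < p; ++i) x[i] = init[i];
  IntegerMatrix out(n_keep, p);
  int total = burn_in + n_keep * thin;
  int kept = 0;
  for (int sweep = 0; sweep < total; ++sweep) {
    for (int i = 0; i < p; ++i) {
      double eta = tau[i];
      for (int j = 0; j < p; ++j)
        if (j != i && x[j]) eta += beta(i, j);
      double pr = 1.0 / (1.0 + std::exp(-eta));
      x[i] = (unif_rand() < pr) ? 1 : 0;
    }
    if (sweep >= burn_in && ((sweep - burn_in + 1) % thin == 0)) {
      if (kept < n_keep) {
        for (int i = 0; i < p; ++i) out(kept, i) = x[i];
        ++kept;
      }
    }
  }
  return out;
}
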