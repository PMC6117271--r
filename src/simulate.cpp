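#include <Rcpp.h>
using namespace Rcpp;

// Barker-rule crowd dynamics on a bin lattice.
//
// One elementary step: pick an agent uniformly at random, pick one of the
// D proposal slots of its bin uniformly, and (if the slot holds a neighbor
// bin with room below n_max) accept the move with probability
// 1/(exp(dH) + 1). Missing-slot and capacity-violating proposals are
// rejected but still consume a step, keeping the proposal kernel symmetric
// at boundaries. One sweep = n_agents steps. Uses R's RNG, so set.seed()
// in R makes runs reproducible.
//
// slots: B x D, 1-based neighbor ids, NA for no neighbor.
// Returns an n_record x B matrix of counts, one row per recorded frame
// (every record_every sweeps, after burn_in sweeps).
// [[Rcpp::export]]
IntegerMatrix cpp_simulate(IntegerMatrix slots, NumericVector v,
                           NumericVector f, int n_max,
                           IntegerVector init_bins, int n_record,
                           int record_every, int burn_in) {
  const int B = slots.nrow();
  const int D = slots.ncol();
  const int nA = init_bins.size();

  std::vector<int> agent_bin(nA);
  std::vector<int> counts(B, 0);
  for (int a = 0; a < nA; ++a) {
    int b = init_bins[a] - 1;
    agent_bin[a] = b;
    counts[b]++;
  }
  for (int b = 0; b < B; ++b) {
    if (counts[b] > n_max) stop("initial placement exceeds N_max in a bin");
  }

  IntegerMatrix out(n_record, B);
  int recorded = 0;
  long long total_sweeps = (long long)burn_in + (long long)n_record * record_every;

  for (long long sweep = 1; sweep <= total_sweeps; ++sweep) {
    for (int step = 0; step < nA; ++step) {
      int a = (int)(unif_rand() * nA);
      if (a == nA) a = nA - 1;
      int from = agent_bin[a];
      int slot = (int)(unif_rand() * D);
      if (slot == D) slot = D - 1;
      int to = slots(from, slot);
      if (to == NA_INTEGER) continue;       // off-lattice proposal
      to -= 1;
      if (counts[to] >= n_max) continue;    // packing limit: dH = +inf
      double dH = (v[to] - v[from])
        + (f[counts[to] + 1] - f[counts[to]])
        + (f[counts[from] - 1] - f[counts[from]]);
      double p = 1.0 / (std::exp(dH) + 1.0);
      if (unif_rand() < p) {
        agent_bin[a] = to;
        counts[from]--;
        counts[to]++;
      }
    }
    if (sweep > burn_in && (sweep - burn_in) % record_every == 0) {
      for (int b = 0; b < B; ++b) out(recorded, b) = counts[b];
      recorded++;
    }
  }
  return out;
}
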