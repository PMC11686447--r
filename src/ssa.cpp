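#include <Rcpp.h>
using namespace Rcpp;

// Gillespie simulation of independent glycans through K cisternae.
//
// The reachable state space and its transitions are precomputed in R; here we
// only run the event loop.  Transitions are grouped by source state
// (adj_start/adj_len index into trans_to/trans_rule, 0-based).  rates is a
// (n_rules_total x K) matrix giving each rule's propensity in each cisterna;
// the last row is the lock-resolution pseudo-reaction.  A glycan whose lock
// is still unresolved after the final cisterna is force-resolved (counted as
// a resolution firing in the last cisterna) so no glycan is lost.
//
// Uses R's RNG, so results are reproducible under set.seed().
// [[Rcpp::export]]
List ssa_simulate_cpp(int n_glycans, int start, int n_states,
                      IntegerVector trans_to, IntegerVector trans_rule,
                      IntegerVector adj_start, IntegerVector adj_len,
                      NumericMatrix rates, NumericVector residence,
                      IntegerVector resolve_to) {
  const int K = residence.size();
  const int n_rules = rates.nrow();
  IntegerVector terminal(n_states);
  IntegerMatrix firing(n_rules, K);
  std::vector<double> prop(64);

  for (int g = 0; g < n_glycans; ++g) {
    int s = start;
    for (int c = 0; c < K; ++c) {
      double t = 0.0;
      const double T = residence[c];
      for (;;) {
        const int a0i = adj_start[s];
        const int len = adj_len[s];
        if (len == 0) break;
        if ((int)prop.size() < len) prop.resize(len);
        double a0 = 0.0;
        for (int j = 0; j < len; ++j) {
          a0 += rates(trans_rule[a0i + j], c);
          prop[j] = a0;
        }
        if (a0 <= 0.0) break;
        t += exp_rand() / a0;
        if (t > T) break;
        const double u = unif_rand() * a0;
        int j = 0;
        while (j < len - 1 && prop[j] < u) ++j;
        firing(trans_rule[a0i + j], c) += 1;
        s = trans_to[a0i + j];
      }
    }
    if (resolve_to[s] != s) {           // force-resolve a dangling lock
      firing(n_rules - 1, K - 1) += 1;
      s = resolve_to[s];
    }
    terminal[s] += 1;
  }
  return List::create(_["terminal_counts"] = terminal,
                      _["firing_counts"] = firing);
}
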