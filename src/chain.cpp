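#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Frame-resolution latent behavior-state chain.
//
// During LED-off frames the chain follows T_off. During LED-on frames it
// follows (1-delta) * T_on + delta * C_pre, where C_pre pulls toward the
// evoked state designated for the cycle's pre-onset state:
//   C_pre(s, .) = (1 - pull) * T_off(s, .) + pull * e_{ctx[pre]}.
// Uses R's RNG so set.seed() governs reproducibility.
// [[Rcpp::export]]
List simulate_chain_cpp(const arma::mat& T_off, const arma::mat& T_on,
                        const IntegerVector& context_map, double delta,
                        double pull, const LogicalVector& led,
                        const IntegerVector& onset_frames, int init_state) {
  const int m = T_off.n_rows;
  const int T = led.size();
  IntegerVector states(T);
  const int n_cycles = onset_frames.size();
  IntegerVector pre_states(n_cycles, NA_INTEGER);
  IntegerVector evoked(n_cycles, NA_INTEGER);

  int s = init_state - 1;  // 0-based
  int cyc = -1;            // current cycle index (0-based)
  int ctx_target = -1;
  GetRNGstate();
  for (int t = 0; t < T; ++t) {
    // record pre-state at each onset (state holding as the LED turns on)
    if (cyc + 1 < n_cycles && t == onset_frames[cyc + 1]) {
      ++cyc;
      pre_states[cyc] = s + 1;
      ctx_target = context_map[s] - 1;
      evoked[cyc] = ctx_target + 1;
    }
    states[t] = s + 1;
    // transition into frame t+1
    double u = unif_rand();
    double acc = 0.0;
    int nxt = m - 1;
    if (led[t]) {
      for (int j = 0; j < m; ++j) {
        double pj = (1.0 - delta) * T_on(s, j) +
                    delta * (1.0 - pull) * T_off(s, j);
        if (j == ctx_target) pj += delta * pull;
        acc += pj;
        if (u <= acc) { nxt = j; break; }
      }
    } else {
      for (int j = 0; j < m; ++j) {
        acc += T_off(s, j);
        if (u <= acc) { nxt = j; break; }
      }
    }
    s = nxt;
  }
  PutRNGstate();
  return List::create(_["states"] = states, _["pre_states"] = pre_states,
                      _["evoked"] = evoked);
}
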