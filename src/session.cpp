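#include <Rcpp.h>
using namespace Rcpp;

// log P(chosen) under the two-option softmax, stable for |d| large.
static inline double log_logistic(double d) {
  if (d > 0.0) return -log1p(std::exp(-d));
  return d - log1p(std::exp(d));
}

// Session log-likelihood of the delta-rule / softmax model.
// chosen, other: 1-based stimulus indices into q0; reward in {0,1}.
// Only the chosen stimulus's value is updated after each trial.
// [[Rcpp::export]]
double cpp_session_loglik(IntegerVector chosen, IntegerVector other,
                          IntegerVector reward, NumericVector q0,
                          double alpha, double beta) {
  std::vector<double> q(q0.begin(), q0.end());
  const int n = chosen.size();
  double ll = 0.0;
  for (int t = 0; t < n; ++t) {
    const int c = chosen[t] - 1;
    const int o = other[t] - 1;
    ll += log_logistic(beta * (q[c] - q[o]));
    q[c] += alpha * (static_cast<double>(reward[t]) - q[c]);
  }
  return ll;
}

// Generative direction: choices from pre-drawn uniforms (RNG stays in R),
// rewards pre-drawn per stimulus per trial (the counterfactual draw for the
// unchosen stimulus exists but is never revealed or used).
// [[Rcpp::export]]
List cpp_simulate_choices(IntegerVector left, IntegerVector right,
                          IntegerVector rew_left, IntegerVector rew_right,
                          NumericVector q0, double alpha, double beta,
                          NumericVector u) {
  std::vector<double> q(q0.begin(), q0.end());
  const int n = left.size();
  IntegerVector choose_left(n), reward(n);
  for (int t = 0; t < n; ++t) {
    const int l = left[t] - 1;
    const int r = right[t] - 1;
    const double d = beta * (q[l] - q[r]);
    const double p_left = (d > 0.0) ? 1.0 / (1.0 + std::exp(-d))
                                    : std::exp(d) / (1.0 + std::exp(d));
    const bool cl = u[t] < p_left;
    const int c = cl ? l : r;
    const int rw = cl ? rew_left[t] : rew_right[t];
    choose_left[t] = cl ? 1 : 0;
    reward[t] = rw;
    q[c] += alpha * (static_cast<double>(rw) - q[c]);
  }
  return List::create(_["choose_left"] = choose_left, _["reward"] = reward);
}

// Value trajectory: Q of every stimulus after each trial (row t = state
// after trial t; row 0 handled by the caller as q0).
// [[Rcpp::export]]
NumericMatrix cpp_q_path(IntegerVector chosen, IntegerVector reward,
                         NumericVector q0, double alpha) {
  const int n = chosen.size();
  const int k = q0.size();
  NumericMatrix out(n, k);
  std::vector<double> q(q0.begin(), q0.end());
  for (int t = 0; t < n; ++t) {
    const int c = chosen[t] - 1;
    q[c] += alpha * (static_cast<double>(reward[t]) - q[c]);
    for (int j = 0; j < k; ++j) out(t, j) = q[j];
  }
  return out;
}
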