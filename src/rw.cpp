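#include <Rcpp.h>
using namespace Rcpp;

// Shared Rescorla-Wagner step used by the fast likelihood and value-replay
// paths. Under risk sensitivity the learning rate is gated on the sign of the
// prediction error; a zero prediction error triggers no update under either
// rate. Under counterfactual updating every unchosen arm moves toward the
// inverse outcome (-r) with the same sign-gated rate applied to its own
// prediction error.
static inline void rw_step(std::vector<double> &V, int a, double r,
                           double alpha_pos, double alpha_neg,
                           bool counterfactual, bool risk_sensitive) {
  const int n_arms = (int)V.size();
  double delta = r - V[a];
  if (delta != 0.0) {
    double ae = risk_sensitive ? (delta > 0 ? alpha_pos : alpha_neg) : alpha_pos;
    V[a] += ae * delta;
  }
  if (counterfactual) {
    for (int u = 0; u < n_arms; ++u) {
      if (u == a) continue;
      double du = (-r) - V[u];
      if (du == 0.0) continue;
      double au = risk_sensitive ? (du > 0 ? alpha_pos : alpha_neg) : alpha_pos;
      V[u] += au * du;
    }
  }
}

// Negative log likelihood of one subject's time-ordered choice/outcome
// sequence under a softmax policy over RW values started at V = 0.
// `chosen` is 0-based.
// [[Rcpp::export]]
double rw_nll_cpp(IntegerVector chosen, NumericVector r, int n_arms,
                  double alpha_pos, double alpha_neg, double beta,
                  bool counterfactual, bool risk_sensitive) {
  const int n = chosen.size();
  std::vector<double> V(n_arms, 0.0);
  double nll = 0.0;
  for (int t = 0; t < n; ++t) {
    int a = chosen[t];
    double m = beta * V[0];
    for (int i = 1; i < n_arms; ++i) m = std::max(m, beta * V[i]);
    double Z = 0.0;
    for (int i = 0; i < n_arms; ++i) Z += std::exp(beta * V[i] - m);
    nll -= (beta * V[a] - m) - std::log(Z);
    rw_step(V, a, r[t], alpha_pos, alpha_neg, counterfactual, risk_sensitive);
  }
  return nll;
}

// Replays a subject's observed sequence and returns the full pre-update value
// matrix (trial x arm): row t holds the expectations in force when choice t
// was made.
// [[Rcpp::export]]
NumericMatrix rw_values_cpp(IntegerVector chosen, NumericVector r, int n_arms,
                            double alpha_pos, double alpha_neg,
                            bool counterfactual, bool risk_sensitive) {
  const int n = chosen.size();
  std::vector<double> V(n_arms, 0.0);
  NumericMatrix out(n, n_arms);
  for (int t = 0; t < n; ++t) {
    for (int i = 0; i < n_arms; ++i) out(t, i) = V[i];
    rw_step(V, chosen[t], r[t], alpha_pos, alpha_neg, counterfactual,
            risk_sensitive);
  }
  return out;
}

// Penalized MAP objective in unconstrained space (logit learning rates,
// log inverse temperature) with a diagonal Gaussian prior; the fitting hot
// path, called thousands of times per EM run.
// [[Rcpp::export]]
double rw_map_obj_cpp(NumericVector theta, IntegerVector chosen,
                      NumericVector r, int n_arms, bool counterfactual,
                      bool risk_sensitive, NumericVector prior_mean,
                      NumericVector prior_var) {
  double ap, an, beta;
  if (risk_sensitive) {
    ap = 1.0 / (1.0 + std::exp(-theta[0]));
    an = 1.0 / (1.0 + std::exp(-theta[1]));
    beta = std::exp(theta[2]);
  } else {
    ap = an = 1.0 / (1.0 + std::exp(-theta[0]));
    beta = std::exp(theta[1]);
  }
  double pen = 0.0;
  for (int d = 0; d < theta.size(); ++d) {
    double z = theta[d] - prior_mean[d];
    pen += 0.5 * z * z / prior_var[d];
  }
  return rw_nll_cpp(chosen, r, n_arms, ap, an, beta, counterfactual,
                    risk_sensitive) + pen;
}
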