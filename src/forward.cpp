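#include <Rcpp.h>
using namespace Rcpp;

// Forward pass of the delta-rule value learner with logistic choice rule.
//
// Q values are stored as q[ctx * 2 + dir] with dir 0 = down, 1 = up.
// For the context-free model the context index is forced to 0 and q has
// length 2. Probabilities are clipped to [1e-12, 1 - 1e-12] only inside
// the log-likelihood accumulation; the returned p_up is unclipped.
// Trials with missing choice (NA) contribute nothing to the likelihood
// and trigger no update (no action was taken).

// [[Rcpp::export(name = ".rl_forward_cpp")]]
List rl_forward_cpp(IntegerVector context, IntegerVector choice_up,
                    NumericVector reward, NumericVector coherence,
                    double beta0, double beta1, double alpha,
                    NumericVector q_init, bool context_dependent) {
  const int T = context.size();
  const double eps = 1e-12;
  const int n_q = q_init.size();
  if (n_q < 2 || n_q % 2 != 0)
    stop("q_init needs an even length >= 2 (one down/up pair per context)");
  if (!context_dependent && n_q != 2)
    stop("the context-free model keeps exactly 2 values");

  std::vector<double> q(q_init.begin(), q_init.end());
  NumericVector p_up(T), rpe(T);
  NumericMatrix q_pre(T, n_q);  // value state before the choice on trial t
  double nll = 0.0;

  for (int t = 0; t < T; ++t) {
    const int c = context_dependent ? context[t] : 0;
    if (c < 0 || 2 * c + 1 >= n_q) stop("context index out of range at trial %d", t + 1);
    for (int j = 0; j < n_q; ++j) q_pre(t, j) = q[j];
    const double dq = q[2 * c + 1] - q[2 * c + 0];
    const double x = beta0 * dq + beta1 * coherence[t];
    const double p = 1.0 / (1.0 + std::exp(-x));
    p_up[t] = p;
    const int m = choice_up[t];
    if (m == NA_INTEGER) {
      rpe[t] = NA_REAL;
      continue;
    }
    double pc = m ? p : 1.0 - p;
    if (pc < eps) pc = eps;
    if (pc > 1.0 - eps) pc = 1.0 - eps;
    nll -= std::log(pc);
    const double d = reward[t] - q[2 * c + m];
    rpe[t] = d;
    q[2 * c + m] += alpha * d;
  }

  return List::create(_["nll"] = nll, _["p_up"] = p_up, _["rpe"] = rpe,
                      _["q_pre"] = q_pre,
                      _["q_final"] = NumericVector(q.begin(), q.end()));
}
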