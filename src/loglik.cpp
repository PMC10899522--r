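#include <Rcpp.h>
using namespace Rcpp;

// Trial-wise log softmax likelihood for one participant-condition cell.
//
// ms, adv, dis, gen: n_trials x max_options matrices of self payoff,
// advantageous inequity, disadvantageous inequity and |inequity| per
// allocation option (columns beyond a trial's own option count are
// ignored via nopt). choice is the 1-based index of the observed option.
// model: 1..5 selects which inequity terms enter the utility (5 == 4).
// [[Rcpp::export]]
NumericVector cell_loglik_cpp(const NumericMatrix& ms,
                              const NumericMatrix& adv,
                              const NumericMatrix& dis,
                              const NumericMatrix& gen,
                              const IntegerVector& nopt,
                              const IntegerVector& choice,
                              double alpha, double beta, double omega,
                              double lambda, int model) {
  const int n = ms.nrow();
  NumericVector out(n);
  for (int t = 0; t < n; ++t) {
    const int J = nopt[t];
    double vmax = R_NegInf;
    // utilities scaled by lambda, two passes: max then sum-exp
    std::vector<double> v(J);
    for (int j = 0; j < J; ++j) {
      double u = ms(t, j);
      switch (model) {
      case 1: u -= alpha * adv(t, j); break;
      case 2: u -= beta * dis(t, j); break;
      case 3: u -= omega * gen(t, j); break;
      default: u -= alpha * adv(t, j) + beta * dis(t, j); break;
      }
      v[j] = lambda * u;
      if (v[j] > vmax) vmax = v[j];
    }
    double s = 0.0;
    for (int j = 0; j < J; ++j) s += std::exp(v[j] - vmax);
    out[t] = v[choice[t] - 1] - vmax - std::log(s);
  }
  return out;
}
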