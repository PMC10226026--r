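#include <Rcpp.h>
using namespace Rcpp;

// Negative log-likelihood of one subject's choices under one delta-rule
// model.  Mirrors the R replay in run_model() but avoids per-trial R
// overhead so that multi-start fitting and recovery studies stay cheap.
//
// model: 0 = dLRI (rate 1/t), 1 = dfLRI (alpha/t), 2 = fLRI (alpha),
//        3 = fLRE (evaluative, chosen entry only).
// context/shown/chosen are 1-based; rows must be in presentation order.
// Choice probabilities are floored at prob_floor inside the log so the
// objective stays finite.
// [[Rcpp::export]]
double rl_nll_cpp(int model, double alpha, double beta,
                  IntegerVector context, IntegerVector shown,
                  IntegerVector chosen,
                  int n_categories, int n_contexts, double prob_floor) {
  const int n = context.size();
  const int J = n_categories;
  std::vector<double> q(static_cast<size_t>(J) * n_contexts, 1.0 / J);
  std::vector<int> tcount(n_contexts, 0);
  std::vector<double> z(J);
  double nll = 0.0;

  for (int i = 0; i < n; ++i) {
    const int c = context[i] - 1;
    const int js = shown[i] - 1;
    const int jc = chosen[i] - 1;
    if (c < 0 || c >= n_contexts || js < 0 || js >= J || jc < 0 || jc >= J)
      stop("index out of range at trial %d", i + 1);
    double *row = &q[static_cast<size_t>(J) * c];

    // softmax probability of the observed choice (max-shifted)
    double m = R_NegInf;
    for (int j = 0; j < J; ++j) {
      z[j] = beta * row[j];
      if (z[j] > m) m = z[j];
    }
    double denom = 0.0;
    for (int j = 0; j < J; ++j) denom += std::exp(z[j] - m);
    double p = std::exp(z[jc] - m) / denom;
    if (p < prob_floor) p = prob_floor;
    nll -= std::log(p);

    // value update (counter advanced to the current trial first)
    tcount[c] += 1;
    if (model == 3) {
      const double r = (jc == js) ? 1.0 : 0.0;
      row[jc] += alpha * (r - row[jc]);
    } else {
      double rate;
      if (model == 0) rate = 1.0 / tcount[c];
      else if (model == 1) rate = alpha / tcount[c];
      else rate = alpha;
      for (int j = 0; j < J; ++j) {
        const double r = (j == js) ? 1.0 : 0.0;
        row[j] += rate * (r - row[j]);
      }
    }
  }
  return nll;
}
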