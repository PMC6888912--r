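#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Log partial likelihood of the counting-process Cox model with a single
// covariate, plus score and observed information. Risk-set membership uses
// half-open intervals: a record (start, stop] is at risk at time t iff
// start < t <= stop. Tied event times are handled by Efron's method.
//
// [[Rcpp::export]]
List cox_pl_cpp(double alpha, NumericVector tstart, NumericVector tstop,
                IntegerVector event, NumericVector x) {
  const int n = tstart.size();
  // distinct event times
  std::vector<double> ev;
  for (int i = 0; i < n; ++i) if (event[i] == 1) ev.push_back(tstop[i]);
  if (ev.empty()) stop("no events in the data");
  std::sort(ev.begin(), ev.end());
  ev.erase(std::unique(ev.begin(), ev.end()), ev.end());

  double ll = 0.0, score = 0.0, info = 0.0;
  for (size_t k = 0; k < ev.size(); ++k) {
    const double u = ev[k];
    double s0 = 0.0, s1 = 0.0, s2 = 0.0;       // risk-set sums
    double d0 = 0.0, d1 = 0.0, d2 = 0.0;       // tied-event sums
    double sumx = 0.0;
    int m = 0;
    for (int i = 0; i < n; ++i) {
      if (tstart[i] < u && u <= tstop[i]) {
        const double e = std::exp(alpha * x[i]);
        s0 += e; s1 += x[i] * e; s2 += x[i] * x[i] * e;
        if (event[i] == 1 && tstop[i] == u) {
          d0 += e; d1 += x[i] * e; d2 += x[i] * x[i] * e;
          sumx += x[i];
          ++m;
        }
      }
    }
    ll += alpha * sumx;
    score += sumx;
    for (int j = 0; j < m; ++j) {
      const double f = (double)j / m;
      const double r0 = s0 - f * d0;
      const double r1 = s1 - f * d1;
      const double r2 = s2 - f * d2;
      ll -= std::log(r0);
      score -= r1 / r0;
      info += r2 / r0 - (r1 / r0) * (r1 / r0);
    }
  }
  return List::create(_["loglik"] = ll, _["score"] = score, _["info"] = info);
}
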