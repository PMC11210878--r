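#include "models.h"
using namespace Rcpp;

// Vectorised evaluation of model coefficients, used by the R-level model
// interface and by tests that probe coefficients on state lattices.

// [[Rcpp::export]]
List model_coefficients_cpp(int tag, NumericVector par,
                            NumericVector q, NumericVector p, NumericVector d) {
  Model m(tag, par);
  const int n = q.size();
  NumericVector fq(n), fp(n), aq(n), ap(n);
  NumericMatrix sq(n, m.nW), sp(n, m.nW);
  NumericVector Bqq(n), Bpp(n), Bqp(n);
  double rowq[3], rowp[3];
  for (int i = 0; i < n; ++i) {
    double fqi, fpi, aqi, api;
    m.rate(q[i], p[i], d[i], fqi, fpi);
    m.drift(q[i], p[i], d[i], aqi, api);
    fq[i] = fqi; fp[i] = fpi; aq[i] = aqi; ap[i] = api;
    m.sigma(q[i], p[i], d[i], rowq, rowp);
    for (int k = 0; k < m.nW; ++k) { sq(i, k) = rowq[k]; sp(i, k) = rowp[k]; }
    double bqq, bpp, bqp;
    m.Bmat(q[i], p[i], d[i], bqq, bpp, bqp);
    Bqq[i] = bqq; Bpp[i] = bpp; Bqp[i] = bqp;
  }
  return List::create(_["fq"] = fq, _["fp"] = fp, _["aq"] = aq, _["ap"] = ap,
                      _["sigma_q"] = sq, _["sigma_p"] = sp,
                      _["Bqq"] = Bqq, _["Bpp"] = Bpp, _["Bqp"] = Bqp);
}
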