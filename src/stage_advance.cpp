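#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Advance one diffusion stage: solve A x^{k+1} = B x^k + s for n_steps steps,
// where A and B are tridiagonal (sub/diag/super diagonals).  A is constant
// within a stage, so its Thomas factorisation is computed once and reused.
// States at the 1-based step indices in `keep` (sorted, ending at n_steps)
// are returned row-wise, together with the running sum of dt-weighted
// boundary fluxes dot(w, x^{k+1}) used by the sink-mode mass audit.
// [[Rcpp::export]]
List stage_advance_cpp(NumericVector al, NumericVector ad, NumericVector au,
                       NumericVector bl, NumericVector bd, NumericVector bu,
                       NumericVector s, NumericVector w, NumericVector x0,
                       int n_steps, IntegerVector keep) {
  const int m = x0.size();
  if (al.size() != m - 1 || au.size() != m - 1 || ad.size() != m ||
      bl.size() != m - 1 || bu.size() != m - 1 || bd.size() != m ||
      s.size() != m || w.size() != m)
    stop("inconsistent tridiagonal system dimensions");

  std::vector<double> cp(m, 0.0), den(m), d(m), b(m);
  std::vector<double> x(x0.begin(), x0.end());

  den[0] = ad[0];
  if (den[0] == 0.0) stop("singular stage system");
  if (m > 1) cp[0] = au[0] / den[0];
  for (int i = 1; i < m; ++i) {
    den[i] = ad[i] - al[i - 1] * cp[i - 1];
    if (den[i] == 0.0) stop("singular stage system");
    if (i < m - 1) cp[i] = au[i] / den[i];
  }

  const int nk = keep.size();
  NumericMatrix states(nk, m);
  NumericVector cumw(nk);
  double acc = 0.0;
  int ki = 0;

  for (int k = 1; k <= n_steps; ++k) {
    for (int i = 0; i < m; ++i) {
      double v = bd[i] * x[i] + s[i];
      if (i > 0) v += bl[i - 1] * x[i - 1];
      if (i < m - 1) v += bu[i] * x[i + 1];
      b[i] = v;
    }
    d[0] = b[0] / den[0];
    for (int i = 1; i < m; ++i) d[i] = (b[i] - al[i - 1] * d[i - 1]) / den[i];
    x[m - 1] = d[m - 1];
    for (int i = m - 2; i >= 0; --i) x[i] = d[i] - cp[i] * x[i + 1];
    for (int i = 0; i < m; ++i) acc += w[i] * x[i];
    if (ki < nk && keep[ki] == k) {
      for (int i = 0; i < m; ++i) states(ki, i) = x[i];
      cumw[ki] = acc;
      ++ki;
    }
  }
  if (ki != nk) stop("keep indices must be sorted, unique and end at n_steps");
  return List::create(_["states"] = states, _["cumw"] = cumw);
}
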