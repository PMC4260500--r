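#include <Rcpp.h>
using namespace Rcpp;

// Burg lattice recursion: forward/backward prediction-error minimisation with
// a Levinson-Durbin coefficient update. Returns coefficients in the
// regression convention x[t] = sum_k ar[k] * x[t-k] + e[t], the final
// prediction-error variance, and the reflection coefficients (all in (-1,1)
// by construction, so the fitted model is stable).
// [[Rcpp::export]]
List burg_cpp(NumericVector x, int order) {
  int n = x.size();
  std::vector<double> f(x.begin(), x.end());
  std::vector<double> b(x.begin(), x.end());
  NumericVector a(order), k(order);
  std::vector<double> a_prev(order, 0.0);

  double E = 0.0;
  for (int i = 0; i < n; ++i) E += x[i] * x[i];
  E /= n;

  for (int m = 0; m < order; ++m) {
    double num = 0.0, den = 0.0;
    for (int i = m + 1; i < n; ++i) {
      num += f[i] * b[i - 1];
      den += f[i] * f[i] + b[i - 1] * b[i - 1];
    }
    double km = (den > 0.0) ? 2.0 * num / den : 0.0;
    k[m] = km;

    for (int j = 0; j < m; ++j) a_prev[j] = a[j];
    for (int j = 0; j < m; ++j) a[j] = a_prev[j] - km * a_prev[m - 1 - j];
    a[m] = km;

    E *= (1.0 - km * km);

    // joint update of forward/backward errors; iterate downwards so b[i-1]
    // is still the stage-m value when f[i] is updated
    for (int i = n - 1; i > m; --i) {
      double fi = f[i], bi = b[i - 1];
      f[i] = fi - km * bi;
      b[i] = bi - km * fi;
    }
  }

  return List::create(_["ar"] = a, _["var"] = E, _["reflection"] = k);
}
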