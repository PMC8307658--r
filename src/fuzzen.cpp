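#include <Rcpp.h>
using namespace Rcpp;

// Mean similarity Phi_m: exponential membership exp(-(d/r)^n_exp) on
// Chebyshev distances between mean-removed templates of length m.
// Templates i = 0..N-m-1 (the same count is used for m and m+1 so the two
// scales are comparable); self-matches are excluded.
static double phi_m(const NumericVector& x, int nt, int m, double r,
                    double n_exp) {
  std::vector<double> mu(nt);
  for (int i = 0; i < nt; ++i) {
    double s = 0.0;
    for (int j = 0; j < m; ++j) s += x[i + j];
    mu[i] = s / m;
  }
  double acc = 0.0;
  for (int i = 0; i < nt; ++i) {
    for (int k = i + 1; k < nt; ++k) {
      double d = 0.0;
      for (int j = 0; j < m; ++j) {
        double diff = std::fabs((x[i + j] - mu[i]) - (x[k + j] - mu[k]));
        if (diff > d) d = diff;
      }
      double z = d / r;
      double e = (n_exp == 2.0) ? std::exp(-z * z)
                                : std::exp(-std::pow(z, n_exp));
      acc += e;
    }
  }
  // average over ordered pairs i != k (symmetric)
  return 2.0 * acc / (static_cast<double>(nt) * (nt - 1));
}

// [[Rcpp::export(name = ".fuzzen_cpp")]]
double fuzzen_cpp(NumericVector x, int m, double r, double n_exp) {
  int N = x.size();
  int nt = N - m - 1 + 1;  // templates shared by scales m and m+1
  double pm = phi_m(x, nt, m, r, n_exp);
  double pm1 = phi_m(x, nt, m + 1, r, n_exp);
  if (pm <= 0.0 || pm1 <= 0.0) return 0.0;
  return std::log(pm) - std::log(pm1);
}
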