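#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Template-matching regularity statistics with Chebyshev distance.
// SampEn excludes self-matches; ApEn includes them (standard definitions).

// [[Rcpp::export(name = ".sampen_cpp")]]
double sampen_cpp(NumericVector xv, int m, double r) {
  const int n = xv.size();
  const int nm = n - m;
  if (nm <= 1) return NA_REAL;
  const double *x = xv.begin();
  double A = 0.0, B = 0.0;  // matches at m+1 and m
  for (int i = 0; i < nm - 1; ++i) {
    for (int j = i + 1; j < nm; ++j) {
      double d = 0.0;
      for (int k = 0; k < m; ++k) {
        double dk = std::fabs(x[i + k] - x[j + k]);
        if (dk > d) d = dk;
      }
      if (d <= r) {
        B += 1.0;
        double dm = std::fabs(x[i + m] - x[j + m]);
        if (dm > d) d = dm;
        if (d <= r) A += 1.0;
      }
    }
  }
  if (B == 0.0 || A == 0.0) {
    // no template matches: return the largest resolvable value
    return std::log((double)nm) + std::log((double)(nm - 1));
  }
  return -std::log(A / B);
}

// [[Rcpp::export(name = ".apen_cpp")]]
double apen_cpp(NumericVector xv, int m, double r) {
  const int n = xv.size();
  if (n - m < 2) return NA_REAL;
  const double *x = xv.begin();
  const int nm1 = n - m + 1;  // templates of length m
  const int nm2 = n - m;      // templates of length m+1
  // per-template match counts, self-matches included
  std::vector<double> cm(nm1, 1.0), cm1(nm2, 1.0);
  for (int i = 0; i < nm1 - 1; ++i) {
    for (int j = i + 1; j < nm1; ++j) {
      double d = 0.0;
      for (int k = 0; k < m; ++k) {
        double dk = std::fabs(x[i + k] - x[j + k]);
        if (dk > d) d = dk;
      }
      if (d <= r) {
        cm[i] += 1.0; cm[j] += 1.0;
        if (i < nm2 && j < nm2) {
          double dm = std::fabs(x[i + m] - x[j + m]);
          if (dm > d) d = dm;
          if (d <= r) { cm1[i] += 1.0; cm1[j] += 1.0; }
        }
      }
    }
  }
  double phi_m = 0.0, phi_m1 = 0.0;
  for (int i = 0; i < nm1; ++i) phi_m += std::log(cm[i] / nm1);
  for (int i = 0; i < nm2; ++i) phi_m1 += std::log(cm1[i] / nm2);
  return phi_m / nm1 - phi_m1 / nm2;
}

// Higuchi fractal dimension: mean normalized curve length L(k) over
// k = 1..kmax, slope of log L(k) against log(1/k).
// [[Rcpp::export(name = ".higuchi_cpp")]]
double higuchi_cpp(NumericVector xv, int kmax) {
  const int n = xv.size();
  const double *x = xv.begin();
  std::vector<double> lk(kmax), lnk(kmax);
  for (int k = 1; k <= kmax; ++k) {
    double Lk = 0.0;
    for (int m = 0; m < k; ++m) {
      const int nmax = (n - 1 - m) / k;
      if (nmax < 1) continue;
      double L = 0.0;
      for (int i = 1; i <= nmax; ++i)
        L += std::fabs(x[m + i * k] - x[m + (i - 1) * k]);
      L *= (double)(n - 1) / ((double)nmax * k * k);
      Lk += L;
    }
    lk[k - 1] = std::log(Lk / k);
    lnk[k - 1] = std::log(1.0 / (double)k);
  }
  double mx = 0.0, my = 0.0;
  for (int i = 0; i < kmax; ++i) { mx += lnk[i]; my += lk[i]; }
  mx /= kmax; my /= kmax;
  double sxy = 0.0, sxx = 0.0;
  for (int i = 0; i < kmax; ++i) {
    sxy += (lnk[i] - mx) * (lk[i] - my);
    sxx += (lnk[i] - mx) * (lnk[i] - mx);
  }
  return sxy / sxx;
}
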