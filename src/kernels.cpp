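#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Template-match counts for sample entropy (Richman & Moorman convention):
// N - m templates are considered at both lengths m and m + 1 so that the
// two counts are taken over the same index range; Chebyshev distance,
// self-matches excluded.  Returns c(A, B) with B = matches at length m,
// A = matches at length m + 1.
// [[Rcpp::export(name = ".sampenCounts")]]
NumericVector sampen_counts(NumericVector x, int m, double r) {
  int n = x.size();
  int nt = n - m;
  double A = 0.0, B = 0.0;
  for (int i = 0; i < nt - 1; ++i) {
    for (int j = i + 1; j < nt; ++j) {
      double d = 0.0;
      bool ok = true;
      for (int k = 0; k < m; ++k) {
        double dd = std::fabs(x[i + k] - x[j + k]);
        if (dd > d) d = dd;
        if (d > r) { ok = false; break; }
      }
      if (ok) {
        B += 1.0;
        if (std::fabs(x[i + m] - x[j + m]) <= r) A += 1.0;
      }
    }
  }
  return NumericVector::create(A, B);
}

// Fuzzy entropy: mean-centred templates, membership exp(-d^nexp / r) with
// Chebyshev d.  Returns log(phi_m) - log(phi_{m+1}) = -log(phi_{m+1}/phi_m).
// Memberships whose exponent exceeds `cut` contribute < 1e-16 relative and
// are skipped; this is below the accuracy of the summation itself.
// [[Rcpp::export(name = ".fuzenValue")]]
double fuzen_value(NumericVector x, int m, double r, double nexp) {
  int n = x.size();
  int nt = n - m;
  long double phm = 0.0L, phm1 = 0.0L;
  std::vector<double> cm((size_t)nt * m), cm1((size_t)nt * (m + 1));
  for (int i = 0; i < nt; ++i) {
    double s = 0.0;
    for (int k = 0; k < m; ++k) s += x[i + k];
    double mu = s / m;
    for (int k = 0; k < m; ++k) cm[(size_t)i * m + k] = x[i + k] - mu;
    s += x[i + m];
    mu = s / (m + 1);
    for (int k = 0; k <= m; ++k) cm1[(size_t)i * (m + 1) + k] = x[i + k] - mu;
  }
  const bool sq = (nexp == 2.0);
  const double cut = 37.0;
  const double dskip = sq ? std::sqrt(cut * r) : std::pow(cut * r, 1.0 / nexp);
  for (int i = 0; i < nt - 1; ++i) {
    const double *ci = &cm[(size_t)i * m], *ci1 = &cm1[(size_t)i * (m + 1)];
    for (int j = i + 1; j < nt; ++j) {
      const double *cj = &cm[(size_t)j * m];
      double d = 0.0;
      for (int k = 0; k < m; ++k) {
        double dd = std::fabs(ci[k] - cj[k]);
        if (dd > d) d = dd;
      }
      if (d < dskip)
        phm += std::exp(-(sq ? d * d : std::pow(d, nexp)) / r);
      const double *cj1 = &cm1[(size_t)j * (m + 1)];
      d = 0.0;
      for (int k = 0; k <= m; ++k) {
        double dd = std::fabs(ci1[k] - cj1[k]);
        if (dd > d) d = dd;
      }
      if (d < dskip)
        phm1 += std::exp(-(sq ? d * d : std::pow(d, nexp)) / r);
    }
  }
  if (phm <= 0.0L || phm1 <= 0.0L) return NA_REAL;
  return (double)(logl((long double)phm) - logl((long double)phm1));
}

// LZ76 exhaustive-parse component count (Kaspar & Schuster 1987).
// [[Rcpp::export(name = ".lz76CountC")]]
int lz76_count_c(IntegerVector s) {
  int n = s.size();
  if (n == 0) return 0;
  if (n == 1) return 1;
  int c = 1, l = 1, i = 0, k = 1, kmax = 1;
  while (true) {
    if (s[i + k - 1] == s[l + k - 1]) {
      k++;
      if (l + k > n) { c++; break; }
    } else {
      if (k > kmax) kmax = k;
      i++;
      if (i == l) {
        c++;
        l += kmax;
        if (l + 1 > n) break;
        i = 0; k = 1; kmax = 1;
      } else {
        k = 1;
      }
    }
  }
  return c;
}
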