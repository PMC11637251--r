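#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Chebyshev distance between length-m windows starting at i and j (0-based).
static inline double cheb(const NumericVector& x, int i, int j, int m) {
  double d = 0.0;
  for (int l = 0; l < m; ++l) {
    double a = std::fabs(x[i + l] - x[j + l]);
    if (a > d) d = a;
  }
  return d;
}

// Phi^m(r) of approximate entropy: mean over i of log(C_i^m), with
// C_i^m the fraction of the N-m+1 windows within tolerance r of window i
// (self-matches included). `strict` switches the match test to d < r.
static double apen_phi(const NumericVector& x, int m, double r, bool strict) {
  int n = x.size();
  int nw = n - m + 1;
  double acc = 0.0;
  for (int i = 0; i < nw; ++i) {
    int cnt = 0;
    for (int j = 0; j < nw; ++j) {
      double d = cheb(x, i, j, m);
      if (strict ? (d < r) : (d <= r)) ++cnt;
    }
    acc += std::log((double)cnt / nw);
  }
  return acc / nw;
}

// [[Rcpp::export]]
double apen_cpp(NumericVector x, int m, double r, bool strict) {
  return apen_phi(x, m, r, strict) - apen_phi(x, m + 1, r, strict);
}

// [[Rcpp::export]]
NumericVector sampen_counts_cpp(NumericVector x, int m, double r) {
  // Richman-Moorman: N - m windows at both lengths, self-pairs excluded.
  int n = x.size();
  int nw = n - m;
  double b = 0.0, a = 0.0;
  for (int i = 0; i < nw; ++i) {
    for (int j = i + 1; j < nw; ++j) {
      if (cheb(x, i, j, m) <= r) {
        b += 1.0;
        if (std::fabs(x[i + m] - x[j + m]) <= r) a += 1.0;
      }
    }
  }
  return NumericVector::create(a, b);
}

// [[Rcpp::export]]
double fuzzen_cpp(NumericVector x, int m, double r, double nfuzz) {
  // Windows are mean-centred; membership exp(-d^nfuzz / r); self-pairs
  // excluded; N - m windows at both lengths.
  int n = x.size();
  int nw = n - m;
  double phi[2];
  for (int s = 0; s < 2; ++s) {
    int mm = m + s;
    NumericMatrix w(nw, mm);
    for (int i = 0; i < nw; ++i) {
      double mu = 0.0;
      for (int l = 0; l < mm; ++l) mu += x[i + l];
      mu /= mm;
      for (int l = 0; l < mm; ++l) w(i, l) = x[i + l] - mu;
    }
    bool sq = nfuzz == 2.0;
    double acc = 0.0;
    for (int i = 0; i < nw; ++i) {
      double rowsum = 0.0;
      for (int j = 0; j < nw; ++j) {
        if (j == i) continue;
        double d = 0.0;
        for (int l = 0; l < mm; ++l) {
          double a = std::fabs(w(i, l) - w(j, l));
          if (a > d) d = a;
        }
        rowsum += std::exp(-(sq ? d * d : std::pow(d, nfuzz)) / r);
      }
      acc += rowsum / (nw - 1);
    }
    phi[s] = acc / nw;
  }
  return std::log(phi[0]) - std::log(phi[1]);
}

// [[Rcpp::export]]
int lz76_cpp(IntegerVector s) {
  // Exhaustive-history phrase count c(n) of the Lempel-Ziv 1976 parsing
  // (Kaspar & Schuster formulation).
  int n = s.size();
  if (n == 0) return 0;
  int c = 1, l = 1, i = 0, k = 1, kmax = 1;
  while (true) {
    if (s[i + k - 1] == s[l + k - 1]) {
      ++k;
      if (l + k > n) { ++c; break; }
    } else {
      if (k > kmax) kmax = k;
      ++i;
      if (i == l) {
        ++c;
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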