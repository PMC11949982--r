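#include <Rcpp.h>
using namespace Rcpp;

// Chebyshev distance between templates starting at i and j (0-based)
static inline double cheb(const NumericVector& x, int i, int j, int m) {
  double d = 0.0;
  for (int k = 0; k < m; ++k) {
    double a = std::fabs(x[i + k] - x[j + k]);
    if (a > d) d = a;
  }
  return d;
}

// Template-match counts for sample entropy: B over length-m templates and A
// over length-(m+1) templates, both across the first n - m start points,
// ordered pairs i != j (each unordered pair counted twice).
// [[Rcpp::export(name = ".sampen_counts")]]
NumericVector sampen_counts(NumericVector x, int m, double r) {
  int nt = x.size() - m;
  double A = 0.0, B = 0.0;
  for (int i = 0; i < nt; ++i) {
    for (int j = i + 1; j < nt; ++j) {
      if (cheb(x, i, j, m) <= r) {
        B += 2.0;
        if (std::fabs(x[i + m] - x[j + m]) <= r) A += 2.0;
      }
    }
  }
  return NumericVector::create(A, B);
}

// Mean exponential membership exp(-(d/r)^nf) over ordered template pairs
// i != j, with each template's own mean removed before the Chebyshev
// distance (fuzzy entropy phi for one template length).
// [[Rcpp::export(name = ".fuzzyen_phi")]]
double fuzzyen_phi(NumericVector x, int m, double r, double nf, int nt) {
  std::vector<double> mu(nt);
  for (int i = 0; i < nt; ++i) {
    double s = 0.0;
    for (int k = 0; k < m; ++k) s += x[i + k];
    mu[i] = s / m;
  }
  double acc = 0.0;
  for (int i = 0; i < nt; ++i) {
    for (int j = i + 1; j < nt; ++j) {
      double d = 0.0;
      for (int k = 0; k < m; ++k) {
        double a = std::fabs((x[i + k] - mu[i]) - (x[j + k] - mu[j]));
        if (a > d) d = a;
      }
      acc += 2.0 * std::exp(-std::pow(d / r, nf));
    }
  }
  return acc / (static_cast<double>(nt) * (nt - 1));
}

// Histogram (nbins equal-width bins over the distance range) of all
// pairwise Chebyshev distances between length-m templates; returns the bin
// counts, or a single zero-length vector marker when all distances equal.
// [[Rcpp::export(name = ".disten_counts")]]
IntegerVector disten_counts(NumericVector x, int m, int nbins) {
  int nt = x.size() - m;
  long long npairs = static_cast<long long>(nt) * (nt - 1) / 2;
  std::vector<double> d(npairs);
  long long idx = 0;
  double lo = R_PosInf, hi = R_NegInf;
  for (int i = 0; i < nt; ++i) {
    for (int j = i + 1; j < nt; ++j) {
      double v = cheb(x, i, j, m);
      d[idx++] = v;
      if (v < lo) lo = v;
      if (v > hi) hi = v;
    }
  }
  if (hi <= lo) return IntegerVector(0);
  IntegerVector counts(nbins);
  double w = (hi - lo) / nbins;
  for (long long k = 0; k < npairs; ++k) {
    int b = static_cast<int>((d[k] - lo) / w);
    if (b >= nbins) b = nbins - 1;
    counts[b] += 1;
  }
  return counts;
}
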