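#include <Rcpp.h>
using namespace Rcpp;

// Sample entropy template counts. Chebyshev distance between delay
// embeddings of length m and m+1; self-matches excluded.
// Returns c(B, A): B = matches at length m, A = matches at length m+1.
// [[Rcpp::export(name = ".sampen_counts_cpp")]]
NumericVector sampen_counts_cpp(NumericVector x, int m, double r) {
  int n = x.size();
  int nm = n - m;                 // templates of length m (first n-m of them
                                  // are extendable to length m+1)
  if (nm - 1 < 1) return NumericVector::create(NA_REAL, NA_REAL);
  double B = 0.0, A = 0.0;
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
  return NumericVector::create(B, A);
}

// Fuzzy entropy phi terms. Templates are mean-centred; membership is
// exp(-(d/r)^n_exp) of the Chebyshev distance. Returns c(phi_m, phi_m1),
// the average pairwise memberships at lengths m and m+1.
// [[Rcpp::export(name = ".fuzzyen_phi_cpp")]]
NumericVector fuzzyen_phi_cpp(NumericVector x, int m, double r, double n_exp) {
  int n = x.size();
  int nm1 = n - m;               // number of (m+1)-length templates
  if (nm1 < 2) return NumericVector::create(NA_REAL, NA_REAL);
  // centred templates of length m and m+1, aligned on the same start index
  NumericMatrix tm(nm1, m), tm1(nm1, m + 1);
  for (int i = 0; i < nm1; ++i) {
    double mu_m = 0.0, mu_m1 = 0.0;
    for (int k = 0; k < m; ++k) mu_m += x[i + k];
    mu_m /= m;
    for (int k = 0; k <= m; ++k) mu_m1 += x[i + k];
    mu_m1 /= (m + 1);
    for (int k = 0; k < m; ++k) tm(i, k) = x[i + k] - mu_m;
    for (int k = 0; k <= m; ++k) tm1(i, k) = x[i + k] - mu_m1;
  }
  double phi_m = 0.0, phi_m1 = 0.0;
  long cnt = 0;
  const bool quad = (n_exp == 2.0);
  for (int i = 0; i < nm1 - 1; ++i) {
    for (int j = i + 1; j < nm1; ++j) {
      double d = 0.0;
      for (int k = 0; k < m; ++k) {
        double dk = std::fabs(tm(i, k) - tm(j, k));
        if (dk > d) d = dk;
      }
      d /= r;
      phi_m += std::exp(quad ? -(d * d) : -std::pow(d, n_exp));
      d = 0.0;
      for (int k = 0; k <= m; ++k) {
        double dk = std::fabs(tm1(i, k) - tm1(j, k));
        if (dk > d) d = dk;
      }
      d /= r;
      phi_m1 += std::exp(quad ? -(d * d) : -std::pow(d, n_exp));
      ++cnt;
    }
  }
  return NumericVector::create(phi_m / cnt, phi_m1 / cnt);
}

// Classic DTW with absolute-difference local cost, full alignment,
// no window. Returns the accumulated cost of the optimal path.
// [[Rcpp::export(name = ".dtw_cost_cpp")]]
double dtw_cost_cpp(NumericVector a, NumericVector b) {
  int n = a.size(), m = b.size();
  std::vector<double> prev(m), cur(m);
  const double inf = std::numeric_limits<double>::infinity();
  for (int j = 0; j < m; ++j) {
    double c = std::fabs(a[0] - b[j]);
    prev[j] = (j == 0) ? c : prev[j - 1] + c;
  }
  for (int i = 1; i < n; ++i) {
    for (int j = 0; j < m; ++j) {
      double c = std::fabs(a[i] - b[j]);
      double best = prev[j];
      if (j > 0) {
        if (prev[j - 1] < best) best = prev[j - 1];
        if (cur[j - 1] < best) best = cur[j - 1];
      }
      cur[j] = c + (best == inf ? 0.0 : best);
    }
    std::swap(prev, cur);
  }
  return prev[m - 1];
}
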