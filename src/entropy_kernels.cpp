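#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Chebyshev distance between raw templates starting at i and j, length m
static inline double cheb(const double* x, int i, int j, int m) {
  double d = 0.0;
  for (int k = 0; k < m; ++k) {
    double a = std::fabs(x[i + k] - x[j + k]);
    if (a > d) d = a;
  }
  return d;
}

// Approximate, sample and fuzzy entropy in one call (they share the
// pairwise template-distance structure). Returns
// (ApEn, SampEn A, SampEn B, FuzzyEn).
//
// ApEn: self-matches included, templates 0..N-m for length m and
//   0..N-m-1 for length m+1; Phi^m = mean_i log(C_i^m).
// SampEn: pair counts over i < j, templates 0..N-m-1 for both lengths.
// FuzzyEn: mean-centered templates, membership exp(-(d/r)^p),
//   phi^m averaged over i != j pairs, templates 0..N-m-1.
// [[Rcpp::export(name = ".template_entropies_cpp")]]
NumericVector template_entropies_cpp(NumericVector xv, int m, double r,
                                     double p) {
  const int N = xv.size();
  const double* x = REAL(xv);
  const int nA = N - m + 1;  // length-m templates (ApEn)
  const int nB = N - m;      // length-(m+1) templates / SampEn count
  std::vector<double> cm(nA, 1.0), cm1(nB, 1.0); // self-match included
  double sampA = 0.0, sampB = 0.0;
  for (int i = 0; i < nA - 1; ++i) {
    for (int j = i + 1; j < nA; ++j) {
      double d = cheb(x, i, j, m);
      bool near = d <= r;
      if (near) {
        cm[i] += 1.0; cm[j] += 1.0;
        if (j < nB) sampB += 1.0;
      }
      if (j < nB) {
        double a = std::fabs(x[i + m] - x[j + m]);
        double d1 = a > d ? a : d;
        if (d1 <= r) {
          cm1[i] += 1.0; cm1[j] += 1.0;
          sampA += 1.0;
        }
      }
    }
  }
  double phim = 0.0, phim1 = 0.0;
  for (int i = 0; i < nA; ++i) phim += std::log(cm[i] / nA);
  for (int i = 0; i < nB; ++i) phim1 += std::log(cm1[i] / nB);
  double apen = phim / nA - phim1 / nB;

  // fuzzy: centered templates of lengths m and m+1, nB of each
  std::vector<double> fm((size_t)nB * m), fm1((size_t)nB * (m + 1));
  for (int i = 0; i < nB; ++i) {
    double mu = 0.0;
    for (int k = 0; k < m; ++k) mu += x[i + k];
    mu /= m;
    for (int k = 0; k < m; ++k) fm[(size_t)i * m + k] = x[i + k] - mu;
    double mu1 = 0.0;
    for (int k = 0; k <= m; ++k) mu1 += x[i + k];
    mu1 /= (m + 1);
    for (int k = 0; k <= m; ++k)
      fm1[(size_t)i * (m + 1) + k] = x[i + k] - mu1;
  }
  const bool p2 = p == 2.0;
  double accm = 0.0, accm1 = 0.0;
  for (int i = 0; i < nB - 1; ++i) {
    for (int j = i + 1; j < nB; ++j) {
      double d = 0.0, d1 = 0.0;
      for (int k = 0; k < m; ++k) {
        double a = std::fabs(fm[(size_t)i * m + k] - fm[(size_t)j * m + k]);
        if (a > d) d = a;
      }
      for (int k = 0; k <= m; ++k) {
        double a = std::fabs(fm1[(size_t)i * (m + 1) + k] -
                             fm1[(size_t)j * (m + 1) + k]);
        if (a > d1) d1 = a;
      }
      double u = d / r, u1 = d1 / r;
      accm += p2 ? std::exp(-u * u) : std::exp(-std::pow(u, p));
      accm1 += p2 ? std::exp(-u1 * u1) : std::exp(-std::pow(u1, p));
    }
  }
  double fphim = 2.0 * accm / ((double)nB * (nB - 1));
  double fphim1 = 2.0 * accm1 / ((double)nB * (nB - 1));
  double fuzzy = (fphim > 0.0 && fphim1 > 0.0)
    ? std::log(fphim) - std::log(fphim1) : NA_REAL;
  return NumericVector::create(apen, sampA, sampB, fuzzy);
}

// Permutation entropy (nats, unnormalized): ordinal patterns of
// consecutive m-tuples at delay tau; ties broken by index order
// (stable ranking). Patterns encoded base-m.
// [[Rcpp::export(name = ".permen_cpp")]]
double permen_cpp(NumericVector xv, int m, int tau) {
  const int N = xv.size();
  const double* x = REAL(xv);
  const int n = N - (m - 1) * tau;
  if (n < 1) return NA_REAL;
  std::unordered_map<long long, int> counts;
  std::vector<int> idx(m);
  for (int t = 0; t < n; ++t) {
    for (int k = 0; k < m; ++k) idx[k] = k;
    // stable insertion sort of indices by (value, index)
    for (int a = 1; a < m; ++a) {
      int key = idx[a];
      double kv = x[t + key * tau];
      int b = a - 1;
      while (b >= 0 && x[t + idx[b] * tau] > kv) {
        idx[b + 1] = idx[b];
        --b;
      }
      idx[b + 1] = key;
    }
    long long code = 0;
    for (int k = 0; k < m; ++k) code = code * m + idx[k];
    counts[code] += 1;
  }
  double H = 0.0;
  for (auto& kv : counts) {
    double q = (double)kv.second / (double)n;
    H -= q * std::log(q);
  }
  return H;
}
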