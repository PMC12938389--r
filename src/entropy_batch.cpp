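// Batched entropy features over many single-channel segments.
// Columns of the input matrix are independent epoch x channel segments;
// one call computes the non-FFT metrics for all of them, avoiding
// per-segment R dispatch in cohort-scale feature extraction.
#include <RcppArmadillo.h>
#include <unordered_map>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

NumericVector template_entropies_cpp(NumericVector xv, int m, double r,
                                     double p);
double permen_cpp(NumericVector xv, int m, int tau);

// rows of result: apen, sampen, fuzzy, perm, sse
// r = r_frac * sd(col) when r_is_frac, else absolute r.
// sse: Hankel window L (already capped by caller), sigma_sq weighting
// optional.
// [[Rcpp::export(name = ".entropy_batch_cpp")]]
NumericMatrix entropy_batch_cpp(NumericMatrix X, int m, double r_tol,
                                bool r_is_frac, double p, int mperm,
                                int tau, int L, bool sse_sigma_sq,
                                LogicalVector which_metrics) {
  const int N = X.nrow(), S = X.ncol();
  const bool do_tmpl = which_metrics[0] || which_metrics[1] ||
    which_metrics[2];
  const bool do_perm = which_metrics[3];
  const bool do_sse = which_metrics[4];
  NumericMatrix out(5, S);
  std::fill(out.begin(), out.end(), NA_REAL);
  const int K = N - L + 1;
  arma::mat H;
  if (do_sse) H.set_size(L, K);
  for (int s = 0; s < S; ++s) {
    NumericVector x = X(_, s);
    // sample SD (n-1 denominator), matching stats::sd
    double mu = 0.0;
    for (int i = 0; i < N; ++i) mu += x[i];
    mu /= N;
    double ss = 0.0;
    for (int i = 0; i < N; ++i) ss += (x[i] - mu) * (x[i] - mu);
    double sdv = std::sqrt(ss / (N - 1));
    if (do_tmpl) {
      if (sdv == 0.0) {
        out(0, s) = 0.0; out(1, s) = 0.0; out(2, s) = 0.0;
      } else {
        double r = r_is_frac ? r_tol * sdv : r_tol;
        NumericVector te = template_entropies_cpp(x, m, r, p);
        out(0, s) = te[0];
        out(1, s) = (te[1] == 0.0 || te[2] == 0.0)
          ? NA_REAL : -std::log(te[1] / te[2]);
        out(2, s) = te[3];
      }
    }
    if (do_perm) out(3, s) = permen_cpp(x, mperm, tau);
    if (do_sse) {
      if (sdv == 0.0 && mu == 0.0) {
        out(4, s) = 0.0;
      } else {
        for (int j = 0; j < K; ++j)
          for (int i = 0; i < L; ++i) H(i, j) = x[i + j];
        arma::vec sv = arma::svd(H);
        if (sse_sigma_sq) sv = arma::square(sv);
        double tot = arma::accu(sv);
        double hent = 0.0;
        for (arma::uword i = 0; i < sv.n_elem; ++i) {
          double q = sv(i) / tot;
          if (q > 0.0) hent -= q * std::log(q);
        }
        out(4, s) = hent;
      }
    }
  }
  return out;
}
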