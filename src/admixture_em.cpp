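// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

using namespace Rcpp;

// EM for the haploid admixture model.
//
// Calls g_il in {0,1,NA}; hidden cluster-of-origin z_il with
// P(z_il = k) = q_ik and P(g_il = 1 | z_il = k) = p_kl.
// E-step: responsibilities r_ilk = q_ik f_kl / sum_k q_ik f_kl where
// f_kl = p_kl^g (1-p_kl)^(1-g).  M-step: q_ik = mean_l r_ilk over observed
// loci; p_kl = sum_i r_ilk g_il / sum_i r_ilk.  Missing cells contribute
// nothing.  The log-likelihood is accumulated in the same pass (for the
// parameters in force *before* the update), so the returned trace must be
// non-decreasing — a violated EM guarantee signals a bug upstream.
//
// G: n x L integer matrix with NA_INTEGER for missing.
// [[Rcpp::export]]
List admixture_em_cpp(const IntegerMatrix G, const arma::mat Q0,
                      const arma::mat P0, const double tol,
                      const int max_iter, const double eps) {
  const int n = G.nrow(), L = G.ncol();
  const int K = Q0.n_cols;
  arma::mat Q = Q0, P = P0;
  std::vector<double> trace;
  trace.reserve(64);
  double ll_prev = -std::numeric_limits<double>::infinity();
  int iter = 0;

  arma::mat Qnum(n, K), Pnum(K, L), Pden(K, L);
  arma::vec r(K);

  for (iter = 1; iter <= max_iter; ++iter) {
    Qnum.zeros(); Pnum.zeros(); Pden.zeros();
    double ll = 0.0;
    for (int l = 0; l < L; ++l) {
      for (int i = 0; i < n; ++i) {
        const int g = G(i, l);
        if (g == NA_INTEGER) continue;
        double s = 0.0;
        for (int k = 0; k < K; ++k) {
          const double f = g ? P(k, l) : 1.0 - P(k, l);
          r[k] = Q(i, k) * f;
          s += r[k];
        }
        if (s < 1e-300) s = 1e-300;
        ll += std::log(s);
        for (int k = 0; k < K; ++k) {
          const double rk = r[k] / s;
          Qnum(i, k) += rk;
          Pden(k, l) += rk;
          if (g) Pnum(k, l) += rk;
        }
      }
    }
    trace.push_back(ll);

    // M-step
    for (int i = 0; i < n; ++i) {
      double tot = arma::accu(Qnum.row(i));
      if (tot > 0) Q.row(i) = Qnum.row(i) / tot;
    }
    for (int k = 0; k < K; ++k) {
      for (int l = 0; l < L; ++l) {
        double p = Pden(k, l) > 1e-300 ? Pnum(k, l) / Pden(k, l) : P(k, l);
        if (p < eps) p = eps;
        if (p > 1.0 - eps) p = 1.0 - eps;
        P(k, l) = p;
      }
    }
    if (ll - ll_prev < tol && iter > 1) break;
    ll_prev = ll;
  }

  return List::create(_["Q"] = Q, _["P"] = P,
                      _["loglik_trace"] = NumericVector(trace.begin(), trace.end()),
                      _["n_iter"] = std::min(iter, max_iter));
}
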