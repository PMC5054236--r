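// Variational E-step and response-coefficient objective for the supervised
// topic model (sLDA with a softmax class response over empirical topic
// frequencies z-bar).
//
// The intractable E_q[log sum_c exp(eta_c' zbar)] in the ELBO is upper-
// bounded by Jensen: log E_q[sum_c exp(eta_c' zbar)], which factorizes over
// word positions because q(z) does:
//   E_q[exp(eta_c' zbar)] = prod_v (phi_v' kappa_c)^{m_v},
//   kappa_c = exp(eta_c / N).
// The per-position phi update additionally uses the tangent bound
// -log x >= -x/zeta - log zeta + 1 (zeta = current value), which makes the
// update a closed-form softmax and keeps coordinate ascent monotone in the
// bounded ELBO.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static double lse(const std::vector<double>& v) {
  double m = v[0];
  for (size_t i = 1; i < v.size(); ++i) if (v[i] > m) m = v[i];
  double s = 0.0;
  for (size_t i = 0; i < v.size(); ++i) s += std::exp(v[i] - m);
  return m + std::log(s);
}

// [[Rcpp::export]]
List slda_estep_cpp(List docs_ids, List docs_cts, NumericMatrix log_beta,
                    NumericMatrix eta, IntegerVector labels, double alpha,
                    int max_inner, double tol, bool keep_phi) {
  const int D = docs_ids.size();
  const int K = log_beta.nrow();
  const int V = log_beta.ncol();
  const int C = eta.nrow();

  NumericMatrix gamma_out(D, K), zbar_out(D, K);
  NumericMatrix ss(K, V);
  NumericVector doc_elbo(D);
  List phi_out(keep_phi ? D : 0);
  bool ok = true;

  std::vector<double> elt(K), lp(K), newphi(K);
  std::vector<double> logE(C), kap(C * K);

  for (int d = 0; d < D; ++d) {
    IntegerVector ids = docs_ids[d];
    NumericVector cts = docs_cts[d];
    const int U = ids.size();
    double N = 0.0;
    for (int v = 0; v < U; ++v) N += cts[v];
    const int lab = labels[d]; // 0-based class, -1 = no label term
    const bool supervised = lab >= 0;

    NumericMatrix phi(U, K);
    std::vector<double> gam(K, alpha + N / K);
    for (int v = 0; v < U; ++v)
      for (int k = 0; k < K; ++k) phi(v, k) = 1.0 / K;

    std::vector<double> s(supervised ? C * U : 0);
    if (supervised) {
      for (int c = 0; c < C; ++c)
        for (int k = 0; k < K; ++k) kap[c * K + k] = std::exp(eta(c, k) / N);
    }

    double bound = R_NegInf;
    for (int it = 0; it < max_inner; ++it) {
      double gsum = 0.0;
      for (int k = 0; k < K; ++k) gsum += gam[k];
      double dgs = R::digamma(gsum);
      for (int k = 0; k < K; ++k) elt[k] = R::digamma(gam[k]) - dgs;

      if (supervised) {
        // refresh s(c,v) and logE_c from the current phi
        for (int c = 0; c < C; ++c) {
          logE[c] = 0.0;
          for (int v = 0; v < U; ++v) {
            double sv = 0.0;
            for (int k = 0; k < K; ++k) sv += phi(v, k) * kap[c * K + k];
            s[c * U + v] = sv;
            logE[c] += cts[v] * std::log(sv);
          }
        }
      }

      for (int v = 0; v < U; ++v) {
        const int w = ids[v];
        if (supervised) {
          double logZ = lse(logE);
          // coefficient of the tangent (per-position) softmax bound
          for (int k = 0; k < K; ++k) lp[k] = 0.0;
          for (int c = 0; c < C; ++c) {
            double r = std::exp(logE[c] - std::log(s[c * U + v]) - logZ);
            for (int k = 0; k < K; ++k) lp[k] -= r * kap[c * K + k];
          }
          for (int k = 0; k < K; ++k)
            lp[k] += elt[k] + log_beta(k, w) + eta(lab, k) / N;
        } else {
          for (int k = 0; k < K; ++k) lp[k] = elt[k] + log_beta(k, w);
        }
        double m = lp[0];
        for (int k = 1; k < K; ++k) if (lp[k] > m) m = lp[k];
        double tot = 0.0;
        for (int k = 0; k < K; ++k) { newphi[k] = std::exp(lp[k] - m); tot += newphi[k]; }
        for (int k = 0; k < K; ++k) newphi[k] /= tot;
        if (supervised) {
          for (int c = 0; c < C; ++c) {
            double sv = 0.0;
            for (int k = 0; k < K; ++k) sv += newphi[k] * kap[c * K + k];
            logE[c] += cts[v] * (std::log(sv) - std::log(s[c * U + v]));
            s[c * U + v] = sv;
          }
        }
        for (int k = 0; k < K; ++k) phi(v, k) = newphi[k];
      }

      // gamma update; convergence on its relative change (the bound is
      // computed once per document, after convergence)
      double delta = 0.0, gtot = 0.0;
      for (int k = 0; k < K; ++k) {
        double g = alpha;
        for (int v = 0; v < U; ++v) g += cts[v] * phi(v, k);
        delta += std::fabs(g - gam[k]);
        gtot += g;
        gam[k] = g;
      }
      if (delta < tol * gtot) break;
    }

    {
      // per-document bound at the converged state
      double gsum2 = 0.0;
      for (int k = 0; k < K; ++k) gsum2 += gam[k];
      double dgs2 = R::digamma(gsum2);
      for (int k = 0; k < K; ++k) elt[k] = R::digamma(gam[k]) - dgs2;
      double b = R::lgammafn(K * alpha) - K * R::lgammafn(alpha);
      for (int k = 0; k < K; ++k) b += (alpha - 1.0) * elt[k];
      b -= R::lgammafn(gsum2);
      for (int k = 0; k < K; ++k)
        b += R::lgammafn(gam[k]) - (gam[k] - 1.0) * elt[k];
      for (int v = 0; v < U; ++v) {
        const int w = ids[v];
        for (int k = 0; k < K; ++k) {
          double ph = phi(v, k);
          if (ph > 0)
            b += cts[v] * ph * (elt[k] + log_beta(k, w) - std::log(ph));
        }
      }
      if (supervised) {
        for (int c = 0; c < C; ++c) {
          logE[c] = 0.0;
          for (int v = 0; v < U; ++v)
            logE[c] += cts[v] * std::log(s[c * U + v]);
        }
        double zk;
        for (int k = 0; k < K; ++k) {
          zk = 0.0;
          for (int v = 0; v < U; ++v) zk += cts[v] * phi(v, k);
          b += eta(lab, k) * zk / N;
        }
        b -= lse(logE);
      }
      bound = b;
      if (!std::isfinite(bound)) ok = false;
    }
    if (!ok) break;

    for (int k = 0; k < K; ++k) {
      double zk = 0.0;
      for (int v = 0; v < U; ++v) zk += cts[v] * phi(v, k);
      zbar_out(d, k) = zk / N;
      gamma_out(d, k) = gam[k];
    }
    for (int v = 0; v < U; ++v)
      for (int k = 0; k < K; ++k) ss(k, ids[v]) += cts[v] * phi(v, k);
    doc_elbo[d] = bound;
    if (keep_phi) phi_out[d] = phi;
  }

  return List::create(
    _["gamma"] = gamma_out, _["zbar"] = zbar_out, _["ss"] = ss,
    _["doc_elbo"] = doc_elbo, _["elbo"] = ok ? sum(doc_elbo) : NA_REAL,
    _["ok"] = ok, _["phi"] = phi_out);
}

// Value and gradient of the response part of the bounded ELBO as a function
// of eta (phi held fixed):
//   R(eta) = sum_d [ eta_{c_d}' zbar_d - log sum_c prod_v (phi_v' kappa_c)^{m_v} ]
// [[Rcpp::export]]
List slda_eta_obj_cpp(List phis, List docs_cts, IntegerVector labels,
                      NumericMatrix eta, NumericVector doc_len) {
  const int D = phis.size();
  const int C = eta.nrow();
  const int K = eta.ncol();
  double value = 0.0;
  NumericMatrix grad(C, K);
  std::vector<double> logE(C), kap(C * K), p(C);

  for (int d = 0; d < D; ++d) {
    NumericMatrix phi = phis[d];
    NumericVector cts = docs_cts[d];
    const int U = phi.nrow();
    const double N = doc_len[d];
    const int lab = labels[d];
    for (int c = 0; c < C; ++c)
      for (int k = 0; k < K; ++k) kap[c * K + k] = std::exp(eta(c, k) / N);

    for (int c = 0; c < C; ++c) logE[c] = 0.0;
    // gradient accumulators: dlogE_c/deta(c,k)
    std::vector<double> dlog(C * K, 0.0);
    for (int v = 0; v < U; ++v) {
      for (int c = 0; c < C; ++c) {
        double sv = 0.0;
        for (int k = 0; k < K; ++k) sv += phi(v, k) * kap[c * K + k];
        logE[c] += cts[v] * std::log(sv);
        for (int k = 0; k < K; ++k)
          dlog[c * K + k] += cts[v] * phi(v, k) * kap[c * K + k] / (N * sv);
      }
    }
    double logZ = lse(logE);
    for (int c = 0; c < C; ++c) p[c] = std::exp(logE[c] - logZ);

    double zk;
    for (int k = 0; k < K; ++k) {
      zk = 0.0;
      for (int v = 0; v < U; ++v) zk += cts[v] * phi(v, k);
      zk /= N;
      value += eta(lab, k) * zk;
      grad(lab, k) += zk;
      for (int c = 0; c < C; ++c)
        grad(c, k) -= p[c] * dlog[c * K + k];
    }
    value -= logZ;
  }
  return List::create(_["value"] = value, _["grad"] = grad);
}
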