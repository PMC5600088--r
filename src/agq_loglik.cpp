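#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Marginal log-likelihood of a binomial-logit mixed model on aggregated
// cluster-period counts, integrated over cluster-level random effects by
// mode-centred (adaptive) Gauss-Hermite quadrature.
//
// Random-effect structure per record, with t the slope covariate:
//   form 0 (random intercept):           eta = eta0 + sigma * s          (d = 1)
//   form 1 (intercept + period slope):   t = z, eta = eta0 + a(t) . s    (d = 2)
//   form 2 (intercept + treatment slope):t = x, eta = eta0 + a(t) . s    (d = 2)
// where s ~ N(0, I_d) and a(t) = L' (1, t) under the log-Cholesky factor
//   L = [[exp(l1), 0], [c21, exp(l2)]],  Sigma = L L'.
// Parameter vector: (mu, beta, theta, l1) for d = 1, (mu, beta, theta,
// l1, c21, l2) for d = 2.

static inline double log1pexp_(double x) {
  if (x > 35.0) return x;
  if (x < -35.0) return std::exp(x);
  return std::log1p(std::exp(x));
}

static inline double expit_(double x) {
  if (x >= 0) {
    double e = std::exp(-x);
    return 1.0 / (1.0 + e);
  }
  double e = std::exp(x);
  return e / (1.0 + e);
}

// binomial log-likelihood part sum_j y eta - n log(1 + e^eta) for one cluster
// at standardized random effect s (length d), plus gradient/hessian of
// h(s) = g(s) - s's/2 when requested.
struct ClusterWork {
  const double* eta0;  // fixed-effect linear predictor per record
  const double* a1;    // random-effect loading, dim 1
  const double* a2;    // random-effect loading, dim 2 (NULL if d == 1)
  const double* y;
  const double* n;
  int nrec;
  int d;

  double h(double s1, double s2) const {
    double out = -0.5 * (s1 * s1 + (d == 2 ? s2 * s2 : 0.0));
    for (int j = 0; j < nrec; ++j) {
      double eta = eta0[j] + a1[j] * s1 + (d == 2 ? a2[j] * s2 : 0.0);
      out += y[j] * eta - n[j] * log1pexp_(eta);
    }
    return out;
  }

  // Newton step pieces at s: gradient g[] and negative-definite hessian H[]
  // (H stored as h11, h12, h22)
  void grad_hess(double s1, double s2, double* g, double* H) const {
    g[0] = -s1; g[1] = (d == 2) ? -s2 : 0.0;
    H[0] = -1.0; H[1] = 0.0; H[2] = (d == 2) ? -1.0 : 0.0;
    for (int j = 0; j < nrec; ++j) {
      double eta = eta0[j] + a1[j] * s1 + (d == 2 ? a2[j] * s2 : 0.0);
      double p = expit_(eta);
      double r = y[j] - n[j] * p;
      double w = n[j] * p * (1.0 - p);
      g[0] += r * a1[j];
      H[0] -= w * a1[j] * a1[j];
      if (d == 2) {
        g[1] += r * a2[j];
        H[1] -= w * a1[j] * a2[j];
        H[2] -= w * a2[j] * a2[j];
      }
    }
  }
};

// find the conditional mode of h by damped Newton; returns mode in s and the
// negative hessian pieces at the mode in Hneg (h11, h12, h22 of -H)
static void find_mode(const ClusterWork& cw, double* s, double* Hneg) {
  double s1 = 0.0, s2 = 0.0;
  double g[2], H[3];
  double hval = cw.h(s1, s2);
  for (int it = 0; it < 50; ++it) {
    cw.grad_hess(s1, s2, g, H);
    double d1, d2 = 0.0;
    if (cw.d == 1) {
      d1 = -g[0] / H[0];
    } else {
      double det = H[0] * H[2] - H[1] * H[1];
      // H negative definite so det > 0; guard anyway
      if (det < 1e-300) det = 1e-300;
      d1 = -( H[2] * g[0] - H[1] * g[1]) / det;
      d2 = -(-H[1] * g[0] + H[0] * g[1]) / det;
    }
    double gnorm = std::fabs(g[0]) + std::fabs(g[1]);
    if (gnorm < 1e-9) break;
    double step = 1.0;
    double n1 = s1, n2 = s2, hnew;
    for (int half = 0; half < 30; ++half) {
      n1 = s1 + step * d1;
      n2 = s2 + step * d2;
      hnew = cw.h(n1, n2);
      if (hnew >= hval - 1e-12) break;
      step *= 0.5;
    }
    if (hnew < hval - 1e-12) break;  // no progress
    s1 = n1; s2 = n2; hval = hnew;
  }
  cw.grad_hess(s1, s2, g, H);
  s[0] = s1; s[1] = s2;
  Hneg[0] = -H[0]; Hneg[1] = -H[1]; Hneg[2] = -H[2];
}

// log-likelihood contributions per cluster; records must be ordered by
// cluster, with cl_start/cl_len giving each cluster's slice (0-based)
// [[Rcpp::export]]
NumericVector agq_cluster_logliks(NumericVector par,
                                  NumericVector y, NumericVector n,
                                  NumericVector z, NumericVector x,
                                  IntegerVector cl_start, IntegerVector cl_len,
                                  int form,
                                  NumericVector gh_nodes, NumericVector gh_logw,
                                  bool include_lchoose) {
  const int d = (form == 0) ? 1 : 2;
  const int nrec_total = y.size();
  const int ncl = cl_start.size();
  const int Q = gh_nodes.size();
  const double mu = par[0], beta = par[1], theta = par[2];

  double L11 = std::exp(par[3]);
  double c21 = (d == 2) ? par[4] : 0.0;
  double L22 = (d == 2) ? std::exp(par[5]) : 0.0;

  std::vector<double> eta0(nrec_total), a1(nrec_total), a2(nrec_total);
  for (int j = 0; j < nrec_total; ++j) {
    eta0[j] = mu + beta * z[j] + theta * x[j];
    double t = (form == 2) ? x[j] : z[j];
    if (d == 1) {
      a1[j] = L11;
    } else {
      // a = L'(1, t) = (L11 + c21 t, L22 t)
      a1[j] = L11 + c21 * t;
      a2[j] = L22 * t;
    }
  }

  NumericVector out(ncl);
  std::vector<double> terms(d == 1 ? Q : Q * Q);

  for (int c = 0; c < ncl; ++c) {
    ClusterWork cw;
    int st = cl_start[c];
    cw.eta0 = &eta0[st]; cw.a1 = &a1[st]; cw.a2 = &a2[st];
    cw.y = &y[st]; cw.n = &n[st];
    cw.nrec = cl_len[c]; cw.d = d;

    double smode[2], Hneg[3];
    find_mode(cw, smode, Hneg);

    double ll;
    if (d == 1) {
      double sigstar = 1.0 / std::sqrt(Hneg[0]);
      double mx = -INFINITY;
      for (int k = 0; k < Q; ++k) {
        double s1 = smode[0] + M_SQRT2 * sigstar * gh_nodes[k];
        terms[k] = gh_logw[k] + gh_nodes[k] * gh_nodes[k] + cw.h(s1, 0.0);
        if (terms[k] > mx) mx = terms[k];
      }
      double sum = 0.0;
      for (int k = 0; k < Q; ++k) sum += std::exp(terms[k] - mx);
      ll = mx + std::log(sum)
         + 0.5 * M_LN2 + std::log(sigstar) - 0.5 * std::log(2.0 * M_PI);
    } else {
      // Qmat = Hneg^{-1}; lower Cholesky C of Qmat
      double det = Hneg[0] * Hneg[2] - Hneg[1] * Hneg[1];
      if (det < 1e-300) det = 1e-300;
      double q11 =  Hneg[2] / det, q12 = -Hneg[1] / det, q22 = Hneg[0] / det;
      double C11 = std::sqrt(q11);
      double C21 = q12 / C11;
      double C22 = std::sqrt(std::max(q22 - C21 * C21, 1e-300));
      double mx = -INFINITY;
      int idx = 0;
      for (int k = 0; k < Q; ++k) {
        for (int l = 0; l < Q; ++l, ++idx) {
          double z1 = gh_nodes[k], z2 = gh_nodes[l];
          double s1 = smode[0] + M_SQRT2 * (C11 * z1);
          double s2 = smode[1] + M_SQRT2 * (C21 * z1 + C22 * z2);
          terms[idx] = gh_logw[k] + gh_logw[l] + z1 * z1 + z2 * z2 + cw.h(s1, s2);
          if (terms[idx] > mx) mx = terms[idx];
        }
      }
      double sum = 0.0;
      for (int k = 0; k < Q * Q; ++k) sum += std::exp(terms[k] - mx);
      ll = mx + std::log(sum)
         + M_LN2 + std::log(C11) + std::log(C22) - std::log(2.0 * M_PI);
    }

    if (include_lchoose) {
      for (int j = 0; j < cw.nrec; ++j)
        ll += R::lchoose(cw.n[j], cw.y[j]);
    }
    out[c] = ll;
  }
  return out;
}

// [[Rcpp::export]]
double agq_nll(NumericVector par,
               NumericVector y, NumericVector n,
               NumericVector z, NumericVector x,
               IntegerVector cl_start, IntegerVector cl_len,
               int form,
               NumericVector gh_nodes, NumericVector gh_logw) {
  NumericVector ll = agq_cluster_logliks(par, y, n, z, x, cl_start, cl_len,
                                         form, gh_nodes, gh_logw, false);
  double s = 0.0;
  for (int i = 0; i < ll.size(); ++i) s += ll[i];
  return -s;
}

// central-difference gradient of agq_nll, computed without R-level overhead
// [[Rcpp::export]]
NumericVector agq_nll_grad(NumericVector par,
                           NumericVector y, NumericVector n,
                           NumericVector z, NumericVector x,
                           IntegerVector cl_start, IntegerVector cl_len,
                           int form,
                           NumericVector gh_nodes, NumericVector gh_logw) {
  int p = par.size();
  NumericVector g(p);
  NumericVector pp = clone(par);
  for (int i = 0; i < p; ++i) {
    double hstep = 1e-5 * std::max(1.0, std::fabs(par[i]));
    pp[i] = par[i] + hstep;
    double f1 = agq_nll(pp, y, n, z, x, cl_start, cl_len, form, gh_nodes, gh_logw);
    pp[i] = par[i] - hstep;
    double f0 = agq_nll(pp, y, n, z, x, cl_start, cl_len, form, gh_nodes, gh_logw);
    pp[i] = par[i];
    g[i] = (f1 - f0) / (2.0 * hstep);
  }
  return g;
}
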