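#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Marginal log-likelihood of the shared-random-effects joint model, with
// the random effects integrated out by (pseudo-adaptive) Gauss-Hermite
// quadrature, plus its analytic gradient.
//
// Working parametrization: beta (pf), lvec = log-Cholesky of Sigma
// (column-wise, log on the diagonal), log sigma_eps, gamma (baseline
// log-hazard parameters), alpha.
//
// The `pack` list carries per-subject sufficient statistics for the
// longitudinal Gaussian part, Gauss-Legendre nodes on (0, T_i) for the
// cumulative hazard, and fixed quadrature nodes b_ik with log-weights
// logw_ik such that the marginal contribution of subject i is
//   log sum_k exp{ logw_ik + ll_long(b_ik) + ll_surv(b_ik) + log phi(b_ik; Sigma) }.
// Baseline families: 0 = constant, 1 = Weibull, 2 = B-spline log hazard.
//
// [[Rcpp::export]]
List jm_loglik_cpp(NumericVector beta, NumericVector lvec, double log_sigma,
                   NumericVector gamma, double alpha, List pack,
                   bool want_grad) {
  const int nsub = as<int>(pack["nsub"]);
  const int d = as<int>(pack["d"]);
  const int pf = as<int>(pack["pf"]);
  const int pg = as<int>(pack["pg"]);
  const int K = as<int>(pack["K"]);
  const int nq = as<int>(pack["nq"]);
  const int family = as<int>(pack["family"]);
  IntegerVector nobs = pack["nobs"];
  NumericVector yty = pack["yty"];
  NumericMatrix Xty = pack["Xty"];
  NumericMatrix XtX = pack["XtX"];
  NumericMatrix Zty = pack["Zty"];
  NumericMatrix ZtX = pack["ZtX"];
  NumericMatrix ZtZ = pack["ZtZ"];
  NumericVector delta = pack["delta"];
  NumericMatrix fT = pack["fT"];
  NumericMatrix gT = pack["gT"];
  NumericVector logT = pack["logT"];
  NumericMatrix BT = pack["BT"];
  NumericMatrix glw = pack["glw"];
  NumericMatrix Fq = pack["Fq"];
  NumericMatrix Gq = pack["Gq"];
  NumericVector logs = pack["logs"];
  NumericMatrix Bs = pack["Bs"];
  NumericMatrix bnod = pack["bnod"];
  NumericMatrix logw = pack["logw"];

  const double sigma = std::exp(log_sigma), sig2 = sigma * sigma;
  const int nl = d * (d + 1) / 2;
  const int npar = pf + nl + 1 + pg + 1;
  const double l2pi = std::log(2.0 * M_PI);
  const double rho = (family == 1) ? std::exp(gamma[1]) : 0.0;

  // lower-triangular Cholesky factor of Sigma, log on the diagonal
  std::vector<double> L(d * d, 0.0);
  {
    int idx = 0;
    for (int j = 0; j < d; ++j) {
      L[j + j * d] = std::exp(lvec[idx++]);
      for (int i2 = j + 1; i2 < d; ++i2) L[i2 + j * d] = lvec[idx++];
    }
  }
  double logdetL = 0.0;
  for (int j = 0; j < d; ++j) logdetL += std::log(L[j + j * d]);

  double total = 0.0;
  NumericVector grad(npar);
  std::vector<double> mk(K), gbuf;
  if (want_grad) gbuf.assign((size_t)K * npar, 0.0);
  std::vector<double> u(d), wv(d), b(d), v(d), eF(pf), eB(pg);
  std::vector<double> eta0(nq), wfix(nq);

  // raw column-major pointers (hot loops below)
  const double* pFq = REAL(Fq);
  const double* pGq = REAL(Gq);
  const double* pBs = REAL(Bs);
  const double* pBnod = REAL(bnod);
  const double* pLogw = REAL(logw);
  const double* pGlw = REAL(glw);
  const double* pLogs = REAL(logs);
  const double* pfT = REAL(fT);
  const double* pgT = REAL(gT);
  const double* pBT = REAL(BT);

  for (int i = 0; i < nsub; ++i) {
    const double* xty = &Xty(0, i);
    const double* xtx = &XtX(0, i);
    const double* zty = &Zty(0, i);
    const double* ztx = &ZtX(0, i);
    const double* ztz = &ZtZ(0, i);

    double q1 = yty[i];
    for (int k = 0; k < pf; ++k) {
      q1 -= 2.0 * beta[k] * xty[k];
      for (int l = 0; l < pf; ++l) q1 += beta[k] * beta[l] * xtx[k + l * pf];
    }
    for (int j = 0; j < d; ++j) {
      double s = zty[j];
      for (int k = 0; k < pf; ++k) s -= ztx[j + k * d] * beta[k];
      v[j] = s;
    }
    const double* fTi = pfT + (size_t)i * pf;
    const double* gTi = pgT + (size_t)i * d;
    double fTb = 0.0;
    for (int k = 0; k < pf; ++k) fTb += beta[k] * fTi[k];

    double logh0T;
    if (family == 0) logh0T = gamma[0];
    else if (family == 1) logh0T = gamma[0] + gamma[1] + (rho - 1.0) * logT[i];
    else {
      logh0T = 0.0;
      const double* bt = pBT + (size_t)i * pg;
      for (int k = 0; k < pg; ++k) logh0T += gamma[k] * bt[k];
    }
    const double* glwi = pGlw + (size_t)i * nq;
    for (int q = 0; q < nq; ++q) {
      const size_t c = (size_t)i * nq + q;
      const double* fq = pFq + c * pf;
      double bf = 0.0;
      for (int k = 0; k < pf; ++k) bf += beta[k] * fq[k];
      wfix[q] = bf;
      double lh;
      if (family == 0) lh = gamma[0];
      else if (family == 1) lh = gamma[0] + gamma[1] + (rho - 1.0) * pLogs[c];
      else {
        lh = 0.0;
        const double* bs = pBs + c * pg;
        for (int k = 0; k < pg; ++k) lh += gamma[k] * bs[k];
      }
      eta0[q] = std::log(glwi[q]) + lh + alpha * bf;
    }

    double mmax = -INFINITY;
    const double* logwi = pLogw + (size_t)i * K;
    for (int k = 0; k < K; ++k) {
      const double* bn = pBnod + ((size_t)i * K + k) * d;
      for (int j = 0; j < d; ++j) b[j] = bn[j];

      double ssr = q1;
      for (int j = 0; j < d; ++j) {
        ssr -= 2.0 * b[j] * v[j];
        for (int l = 0; l < d; ++l) ssr += b[j] * b[l] * ztz[j + l * d];
      }
      const double ll_long = -0.5 * nobs[i] * (l2pi + 2.0 * log_sigma)
                             - ssr / (2.0 * sig2);

      double bgT = 0.0;
      for (int j = 0; j < d; ++j) bgT += b[j] * gTi[j];
      const double wT = fTb + bgT;

      double cum = 0.0, sum_ew = 0.0, sum_els = 0.0;
      if (want_grad) {
        std::fill(eF.begin(), eF.end(), 0.0);
        std::fill(eB.begin(), eB.end(), 0.0);
      }
      for (int q = 0; q < nq; ++q) {
        const size_t c = (size_t)i * nq + q;
        const double* gq = pGq + c * d;
        double bg = 0.0;
        for (int j = 0; j < d; ++j) bg += b[j] * gq[j];
        const double e = std::exp(eta0[q] + alpha * bg);
        cum += e;
        if (want_grad) {
          sum_ew += e * (wfix[q] + bg);
          if (family == 1) sum_els += e * pLogs[c];
          else if (family == 2) {
            const double* bs = pBs + c * pg;
            for (int k2 = 0; k2 < pg; ++k2) eB[k2] += e * bs[k2];
          }
          const double* fq = pFq + c * pf;
          for (int k2 = 0; k2 < pf; ++k2) eF[k2] += e * fq[k2];
        }
      }
      const double ll_surv = delta[i] * (logh0T + alpha * wT) - cum;

      for (int j = 0; j < d; ++j) {
        double s = b[j];
        for (int l = 0; l < j; ++l) s -= L[j + l * d] * u[l];
        u[j] = s / L[j + j * d];
      }
      double uu = 0.0;
      for (int j = 0; j < d; ++j) uu += u[j] * u[j];
      const double logphi = -0.5 * d * l2pi - logdetL - 0.5 * uu;

      const double m = logwi[k] + ll_long + ll_surv + logphi;
      mk[k] = m;
      if (m > mmax) mmax = m;

      if (want_grad) {
        double* g = &gbuf[(size_t)k * npar];
        int p = 0;
        for (int k2 = 0; k2 < pf; ++k2) {
          double dl = xty[k2];
          for (int l = 0; l < pf; ++l) dl -= xtx[k2 + l * pf] * beta[l];
          for (int j = 0; j < d; ++j) dl -= ztx[j + k2 * d] * b[j];
          g[p++] = dl / sig2 + alpha * (delta[i] * fTi[k2] - eF[k2]);
        }
        // d log phi / d (log-Cholesky), via w = L^{-T} u
        for (int j = d - 1; j >= 0; --j) {
          double s = u[j];
          for (int l = j + 1; l < d; ++l) s -= L[l + j * d] * wv[l];
          wv[j] = s / L[j + j * d];
        }
        for (int j = 0; j < d; ++j) {
          g[p++] = -1.0 + L[j + j * d] * wv[j] * u[j];
          for (int r = j + 1; r < d; ++r) g[p++] = wv[r] * u[j];
        }
        g[p++] = -(double)nobs[i] + ssr / sig2;
        if (family == 0) {
          g[p++] = delta[i] - cum;
        } else if (family == 1) {
          g[p++] = delta[i] - cum;
          g[p++] = delta[i] * (1.0 + rho * logT[i]) - (cum + rho * sum_els);
        } else {
          const double* bt = pBT + (size_t)i * pg;
          for (int k2 = 0; k2 < pg; ++k2)
            g[p++] = delta[i] * bt[k2] - eB[k2];
        }
        g[p++] = delta[i] * wT - sum_ew;
      }
    }

    double se = 0.0;
    for (int k = 0; k < K; ++k) se += std::exp(mk[k] - mmax);
    const double lli = mmax + std::log(se);
    total += lli;
    if (want_grad && R_finite(lli)) {
      for (int k = 0; k < K; ++k) {
        const double pk = std::exp(mk[k] - lli);
        const double* g = &gbuf[(size_t)k * npar];
        for (int p = 0; p < npar; ++p) grad[p] += pk * g[p];
      }
    }
  }
  if (want_grad)
    return List::create(_["loglik"] = total, _["grad"] = grad);
  return List::create(_["loglik"] = total);
}
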