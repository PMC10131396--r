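// Core fitter for the L1-penalized random-intercept linear mixed model.
//
// Mirrors the module contract: block coordinate descent with
// soft-thresholding on the whitened fixed-effect problem, alternating with
// an exact profiled-ML variance-component update (1-D search over
// phi = tau2 / sigma2), until the largest coefficient change falls below
// `tol` or `max_iter` iterations. Crossproducts are carried so a CD sweep
// costs O(p^2) regardless of n.

#include <Rcpp.h>
using namespace Rcpp;

static double prof_s2(double phi, double ssq, const NumericVector& sr,
                      const NumericVector& nj, int n, double floor_s2) {
  double acc = 0.0;
  for (int j = 0; j < sr.size(); ++j)
    acc += phi * sr[j] * sr[j] / (1.0 + nj[j] * phi);
  double s2 = (ssq - acc) / n;
  return s2 > floor_s2 ? s2 : floor_s2;
}

static double prof_nll(double phi, double ssq, const NumericVector& sr,
                       const NumericVector& nj, int n, double floor_s2) {
  double out = n * std::log(prof_s2(phi, ssq, sr, nj, n, floor_s2));
  for (int j = 0; j < nj.size(); ++j) out += std::log1p(nj[j] * phi);
  return out;
}

// golden-section minimisation of the profile negative log-likelihood over
// phi in [0, hi], then compared against the phi = 0 boundary
static double best_phi(double ssq, const NumericVector& sr,
                       const NumericVector& nj, int n, double floor_s2) {
  const double gr = 0.6180339887498949;
  double a = 0.0, b = 1e4;
  double c = b - gr * (b - a), d = a + gr * (b - a);
  double fc = prof_nll(c, ssq, sr, nj, n, floor_s2);
  double fd = prof_nll(d, ssq, sr, nj, n, floor_s2);
  for (int it = 0; it < 120 && (b - a) > 1e-12 * (1.0 + b); ++it) {
    if (fc < fd) {
      b = d; d = c; fd = fc;
      c = b - gr * (b - a);
      fc = prof_nll(c, ssq, sr, nj, n, floor_s2);
    } else {
      a = c; c = d; fc = fd;
      d = a + gr * (b - a);
      fd = prof_nll(d, ssq, sr, nj, n, floor_s2);
    }
  }
  double phi = 0.5 * (a + b);
  if (prof_nll(0.0, ssq, sr, nj, n, floor_s2) <=
      prof_nll(phi, ssq, sr, nj, n, floor_s2))
    return 0.0;
  return phi;
}

// [[Rcpp::export(name = ".plmm_fit_cpp")]]
List plmm_fit_cpp(NumericVector y, NumericMatrix xs, IntegerVector gi,
                  double lambda, int max_iter, double tol,
                  Nullable<List> start) {
  const int n = y.size();
  const int p = xs.ncol();

  // group sizes
  int G = 0;
  for (int i = 0; i < n; ++i) G = std::max(G, gi[i]);
  NumericVector nj(G);
  for (int i = 0; i < n; ++i) nj[gi[i] - 1] += 1.0;

  // response variance (degenerate responses short-circuit)
  double ymean = mean(y);
  double vy_raw = 0.0;
  for (int i = 0; i < n; ++i) vy_raw += (y[i] - ymean) * (y[i] - ymean);
  vy_raw /= (n - 1);
  if (!R_finite(vy_raw) || vy_raw == 0.0) {
    return List::create(_["intercept"] = ymean,
                        _["beta"] = NumericVector(p),
                        _["u"] = NumericVector(G),
                        _["sigma2"] = 0.0, _["tau2"] = 0.0,
                        _["n_iter"] = 0, _["converged"] = true,
                        _["bic"] = R_NegInf, _["rss"] = 0.0);
  }

  // standardized response scale (tolerance is scale-free)
  const double sy = std::sqrt(vy_raw);
  NumericVector ys(n);
  for (int i = 0; i < n; ++i) ys[i] = y[i] / sy;
  const double lam = lambda / sy;
  const double floor_s2 = 1e-12;

  // group means and crossproducts
  NumericMatrix xbar(G, p);
  NumericVector ybar(G);
  for (int i = 0; i < n; ++i) {
    int g = gi[i] - 1;
    ybar[g] += ys[i];
    for (int k = 0; k < p; ++k) xbar(g, k) += xs(i, k);
  }
  for (int g = 0; g < G; ++g) {
    ybar[g] /= nj[g];
    for (int k = 0; k < p; ++k) xbar(g, k) /= nj[g];
  }
  NumericMatrix xtx(p, p);
  NumericVector xty(p);
  for (int k = 0; k < p; ++k) {
    for (int l = k; l < p; ++l) {
      double acc = 0.0;
      for (int i = 0; i < n; ++i) acc += xs(i, k) * xs(i, l);
      xtx(k, l) = acc; xtx(l, k) = acc;
    }
    double acy = 0.0;
    for (int i = 0; i < n; ++i) acy += xs(i, k) * ys[i];
    xty[k] = acy;
  }

  double b0 = mean(ys);
  NumericVector beta(p);
  double sigma2 = 1.0, tau2 = 0.1;
  if (start.isNotNull()) {
    List st(start);
    b0 = as<double>(st["b0"]) / sy;
    NumericVector sb = st["beta"];
    for (int k = 0; k < p; ++k) beta[k] = sb[k] / sy;
    sigma2 = as<double>(st["sigma2"]) / vy_raw;
    tau2 = as<double>(st["tau2"]) / vy_raw;
  }

  NumericVector u(G), theta(G), w(G), omth2(G);
  NumericVector gxty(p), cx(p), dg(p), prev(p + 1);
  NumericMatrix gxtx(p, p);
  bool converged = false;
  int it = 0;
  double phi = 0.0;

  while (true) {
    ++it;
    prev[0] = b0;
    for (int k = 0; k < p; ++k) prev[k + 1] = beta[k];

    double cc = 0.0, cy = 0.0;
    for (int g = 0; g < G; ++g) {
      theta[g] = 1.0 - std::sqrt(sigma2 / (sigma2 + nj[g] * tau2));
      w[g] = theta[g] * (2.0 - theta[g]) * nj[g];
      omth2[g] = (1.0 - theta[g]) * (1.0 - theta[g]) * nj[g];
      cc += omth2[g];
      cy += omth2[g] * ybar[g];
    }
    for (int k = 0; k < p; ++k) {
      double a1 = 0.0, a2 = 0.0;
      for (int g = 0; g < G; ++g) {
        a1 += xbar(g, k) * w[g] * ybar[g];
        a2 += xbar(g, k) * omth2[g];
      }
      gxty[k] = xty[k] - a1;
      cx[k] = a2;
      for (int l = k; l < p; ++l) {
        double a3 = 0.0;
        for (int g = 0; g < G; ++g) a3 += xbar(g, k) * xbar(g, l) * w[g];
        gxtx(k, l) = xtx(k, l) - a3;
        gxtx(l, k) = gxtx(k, l);
      }
      dg[k] = gxtx(k, k);
    }

    // coordinate descent with soft-thresholding; intercept unpenalized
    for (int sweep = 0; sweep < 100; ++sweep) {
      double delta = 0.0;
      double z0 = cy;
      for (int k = 0; k < p; ++k) z0 -= cx[k] * beta[k];
      z0 /= cc;
      delta = std::max(delta, std::fabs(z0 - b0));
      b0 = z0;
      for (int k = 0; k < p; ++k) {
        if (dg[k] <= 0.0) continue;
        double zk = gxty[k] - cx[k] * b0 + dg[k] * beta[k];
        for (int l = 0; l < p; ++l) zk -= gxtx(l, k) * beta[l];
        double bk = 0.0;
        double az = std::fabs(zk) - lam;
        if (az > 0.0) bk = (zk > 0 ? az : -az) / dg[k];
        if (bk != beta[k]) {
          delta = std::max(delta, std::fabs(bk - beta[k]));
          beta[k] = bk;
        }
      }
      if (delta < tol / 2.0) break;
    }

    // exact profiled-ML variance-component update at the current residual
    NumericVector sr(G);
    double ssq = 0.0;
    for (int i = 0; i < n; ++i) {
      double ri = ys[i] - b0;
      for (int k = 0; k < p; ++k) ri -= xs(i, k) * beta[k];
      sr[gi[i] - 1] += ri;
      ssq += ri * ri;
    }
    phi = best_phi(ssq, sr, nj, n, floor_s2);
    sigma2 = prof_s2(phi, ssq, sr, nj, n, floor_s2);
    tau2 = phi * sigma2;
    for (int g = 0; g < G; ++g)
      u[g] = (nj[g] * phi / (1.0 + nj[g] * phi)) * (sr[g] / nj[g]);

    double chg = std::fabs(b0 - prev[0]);
    for (int k = 0; k < p; ++k)
      chg = std::max(chg, std::fabs(beta[k] - prev[k + 1]));
    if (chg < tol) { converged = true; break; }
    if (it >= max_iter) break;
  }

  // marginal Gaussian log-likelihood for BIC (V_j = sigma2 I + tau2 J)
  NumericVector sr(G);
  double ssq = 0.0;
  for (int i = 0; i < n; ++i) {
    double ri = ys[i] - b0;
    for (int k = 0; k < p; ++k) ri -= xs(i, k) * beta[k];
    sr[gi[i] - 1] += ri;
    ssq += ri * ri;
  }
  double logdet = 0.0, quad = 0.0;
  for (int g = 0; g < G; ++g) {
    logdet += (nj[g] - 1.0) * std::log(sigma2) +
      std::log(sigma2 + nj[g] * tau2);
    quad += tau2 * sr[g] * sr[g] / (sigma2 + nj[g] * tau2);
  }
  quad = (ssq - quad) / sigma2;
  double ll = -0.5 * (n * std::log(2.0 * M_PI) + logdet + quad) -
    n * std::log(sy);
  int nnz = 0;
  for (int k = 0; k < p; ++k) if (beta[k] != 0.0) ++nnz;
  double bic = -2.0 * ll + std::log((double) n) * (nnz + 3);

  NumericVector beta_out(p), u_out(G);
  for (int k = 0; k < p; ++k) beta_out[k] = beta[k] * sy;
  for (int g = 0; g < G; ++g) u_out[g] = u[g] * sy;
  return List::create(_["intercept"] = b0 * sy,
                      _["beta"] = beta_out,
                      _["u"] = u_out,
                      _["sigma2"] = sigma2 * vy_raw,
                      _["tau2"] = tau2 * vy_raw,
                      _["n_iter"] = it, _["converged"] = converged,
                      _["bic"] = bic, _["rss"] = ssq * vy_raw);
}
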