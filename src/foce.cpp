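// FOCE-with-interaction marginal likelihood for the two-compartment
// population model with lognormal inter-individual variability and a
// proportional residual error.
//
// Per subject the inner problem finds the conditional mode eta-hat of
//   h(eta) = sum_j [ (y_j - f_j)^2 / (sigma^2 f_j^2) + log(sigma^2 f_j^2) ]
//            + eta' Omega^-1 eta
// (Omega diagonal) by damped Gauss-Newton with the classic weighted
// least-squares curvature  2 J' W J + 2 Omega^-1, W = diag(1/(sigma^2 f^2)).
// The marginal -2 log-likelihood then uses the first-order expansion of f
// around eta-hat, with the residual variance evaluated at eta-hat (the
// "interaction" term):
//   C   = J Omega J' + diag(sigma^2 f(eta-hat)^2)
//   e   = y - f(eta-hat) + J eta-hat
//   -2LL_i = n_i log(2*pi) + log|C| + e' C^-1 e
// which collapses to the exact proportional-error Gaussian -2LL when no
// random effects are present.

#define ARMA_WARN_LEVEL 0
#include <RcppArmadillo.h>
#include "pk2.h"
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static arma::vec conc_sub(const arma::vec &t, const double *p, // V,V2,CL,Q
                          const arma::vec &ds, const arma::vec &da,
                          const arma::vec &dr) {
  pk2::Macro m = pk2::macro_constants(p[0], p[1], p[2], p[3]);
  arma::vec out(t.n_elem, arma::fill::zeros);
  for (arma::uword d = 0; d < ds.n_elem; ++d) {
    double D = da[d] / dr[d];
    for (arma::uword i = 0; i < t.n_elem; ++i)
      out[i] += pk2::event_conc(m, dr[d], D, t[i] - ds[d]);
  }
  return out;
}

// individual parameters: typical values tp (length 4) scaled by exp(eta) on
// the entries listed in map (0-based into V,V2,CL,Q)
static void indiv_pars(const double *tp, const arma::vec &eta,
                       const arma::ivec &map, double *out) {
  for (int k = 0; k < 4; ++k) out[k] = tp[k];
  for (arma::uword j = 0; j < map.n_elem; ++j) out[map[j]] *= std::exp(eta[j]);
}

static const double FLOOR = 1e-12;

static double h_obj(const arma::vec &y, const arma::vec &f,
                    const arma::vec &eta, const arma::vec &w2inv,
                    double sig2) {
  double h = 0.0;
  for (arma::uword j = 0; j < y.n_elem; ++j) {
    double fj = std::max(f[j], FLOOR);
    double v = sig2 * fj * fj;
    double r = y[j] - fj;
    h += r * r / v + std::log(v);
  }
  for (arma::uword k = 0; k < eta.n_elem; ++k) h += eta[k] * eta[k] * w2inv[k];
  return h;
}

// central-difference Jacobian df/deta at eta
static arma::mat jac_eta(const arma::vec &t, const double *tp,
                         const arma::vec &eta, const arma::ivec &map,
                         const arma::vec &ds, const arma::vec &da,
                         const arma::vec &dr) {
  const double hstep = 1e-4;
  arma::mat J(t.n_elem, eta.n_elem);
  double p[4];
  for (arma::uword k = 0; k < eta.n_elem; ++k) {
    arma::vec ep = eta, em = eta;
    ep[k] += hstep; em[k] -= hstep;
    indiv_pars(tp, ep, map, p);
    arma::vec fp = conc_sub(t, p, ds, da, dr);
    indiv_pars(tp, em, map, p);
    arma::vec fm = conc_sub(t, p, ds, da, dr);
    J.col(k) = (fp - fm) / (2 * hstep);
  }
  return J;
}

// [[Rcpp::export(name = ".foce_ofv_cpp")]]
List foce_ofv_cpp(List obs_t, List obs_y,
                  List dose_start, List dose_amt, List dose_rate,
                  NumericMatrix tp_mat, IntegerVector eta_map,
                  NumericVector omega2, double sigma,
                  NumericMatrix eta_start, bool detail = false,
                  int maxit = 100) {
  const int n_sub = obs_t.size();
  const int q = eta_map.size();
  const double sig2 = sigma * sigma;
  const double LOG2PI = std::log(2.0 * M_PI);

  arma::ivec map(q);
  arma::vec w2(q), w2inv(q);
  for (int k = 0; k < q; ++k) {
    map[k] = eta_map[k];
    w2[k] = omega2[k];
    w2inv[k] = 1.0 / omega2[k];
  }

  arma::vec ofv_i(n_sub, arma::fill::zeros);
  arma::mat eta_out(n_sub, q, arma::fill::zeros);
  IntegerVector conv(n_sub, 1);
  List f_hat_out(n_sub), jac_out(n_sub), pred0_out(n_sub);

  double ofv = 0.0;
  double p[4];
  for (int i = 0; i < n_sub; ++i) {
    arma::vec t = as<arma::vec>(obs_t[i]);
    arma::vec y = as<arma::vec>(obs_y[i]);
    arma::vec ds = as<arma::vec>(dose_start[i]);
    arma::vec da = as<arma::vec>(dose_amt[i]);
    arma::vec dr = as<arma::vec>(dose_rate[i]);
    const double *tp = &tp_mat(i, 0);
    double tpv[4] = { tp_mat(i,0), tp_mat(i,1), tp_mat(i,2), tp_mat(i,3) };
    (void)tp;
    const int n = t.n_elem;

    if (q == 0) { // pure fixed-effects extended least squares
      arma::vec f = conc_sub(t, tpv, ds, da, dr);
      double l = n * LOG2PI;
      for (int j = 0; j < n; ++j) {
        double fj = std::max(f[j], FLOOR);
        double v = sig2 * fj * fj;
        double r = y[j] - fj;
        l += std::log(v) + r * r / v;
      }
      ofv_i[i] = l;
      ofv += l;
      if (detail) {
        f_hat_out[i] = wrap(f);
        pred0_out[i] = wrap(f);
        jac_out[i] = NumericMatrix(n, 0);
      }
      continue;
    }

    // ---- inner problem: damped Gauss-Newton from the warm start ----
    arma::vec eta(q);
    for (int k = 0; k < q; ++k) eta[k] = eta_start(i, k);
    indiv_pars(tpv, eta, map, p);
    arma::vec f = conc_sub(t, p, ds, da, dr);
    double h = h_obj(y, f, eta, w2inv, sig2);
    if (!std::isfinite(h)) { eta.zeros(); indiv_pars(tpv, eta, map, p);
      f = conc_sub(t, p, ds, da, dr); h = h_obj(y, f, eta, w2inv, sig2); }

    double lambda = 1e-4;
    bool ok = false;
    for (int it = 0; it < maxit; ++it) {
      arma::mat J = jac_eta(t, tpv, eta, map, ds, da, dr);
      // gradient of h
      arma::vec g(q, arma::fill::zeros);
      arma::mat H(q, q, arma::fill::zeros);
      for (int j = 0; j < n; ++j) {
        double fj = std::max(f[j], FLOOR);
        double r = y[j] - fj;
        double winv = 1.0 / (sig2 * fj * fj);
        for (int k = 0; k < q; ++k) {
          // d/deta_k of r^2/(sig2 f^2) + log(sig2 f^2)
          g[k] += (-2.0 * r * winv - 2.0 * r * r * winv / fj + 2.0 / fj) * J(j, k);
          for (int l = 0; l <= k; ++l)
            H(k, l) += 2.0 * winv * J(j, k) * J(j, l);
        }
      }
      for (int k = 0; k < q; ++k) {
        g[k] += 2.0 * eta[k] * w2inv[k];
        H(k, k) += 2.0 * w2inv[k];
        for (int l = 0; l < k; ++l) H(l, k) = H(k, l);
      }
      double gmax = arma::abs(g).max();
      if (gmax < 1e-8 * (1.0 + std::fabs(h))) { ok = true; break; }

      bool accepted = false;
      for (int tries = 0; tries < 12 && !accepted; ++tries) {
        arma::mat Hd = H;
        Hd.diag() += lambda;
        arma::vec step;
        bool solved = false;
        try {
          solved = arma::solve(step, Hd, -g, arma::solve_opts::likely_sympd +
                                             arma::solve_opts::no_approx);
        } catch (...) { solved = false; }
        if (solved && !step.is_finite()) solved = false;
        if (solved) {
          arma::vec etan = eta + step;
          indiv_pars(tpv, etan, map, p);
          arma::vec fn = conc_sub(t, p, ds, da, dr);
          double hn = h_obj(y, fn, etan, w2inv, sig2);
          if (std::isfinite(hn) && hn <= h + 1e-12) {
            if (h - hn < 1e-10 * (1.0 + std::fabs(h)) &&
                arma::norm(step, "inf") < 1e-8) { ok = true; }
            eta = etan; f = fn; h = hn;
            lambda = std::max(lambda / 3.0, 1e-8);
            accepted = true;
          }
        }
        if (!accepted) lambda *= 10.0;
      }
      if (!accepted || ok) { if (accepted) ok = true; break; }
    }
    // a stalled line search still leaves a usable (best-so-far) mode;
    // only a non-finite h is a hard failure
    if (!std::isfinite(h)) { conv[i] = 0; ofv_i[i] = R_PosInf; ofv = R_PosInf; continue; }
    conv[i] = ok ? 1 : 2;

    // ---- FOCE-I assembly at the mode ----
    arma::mat J = jac_eta(t, tpv, eta, map, ds, da, dr);
    arma::vec fh = f;
    for (int j = 0; j < n; ++j) fh[j] = std::max(fh[j], FLOOR);
    arma::mat C = J * arma::diagmat(w2) * J.t();
    C = 0.5 * (C + C.t()); // enforce exact symmetry before factorisation
    C.diag() += sig2 * arma::square(fh);
    arma::vec e = y - fh + J * eta;
    if (!C.is_finite() || !e.is_finite()) {
      conv[i] = 0; ofv_i[i] = R_PosInf; ofv = R_PosInf; continue;
    }
    double ld, sign;
    arma::mat L;
    if (!arma::chol(L, C, "lower")) {
      C.diag() += 1e-10 * arma::mean(C.diag());
      if (!arma::chol(L, C, "lower")) { conv[i] = 0; ofv_i[i] = R_PosInf; ofv = R_PosInf; continue; }
    }
    ld = 2.0 * arma::sum(arma::log(L.diag()));
    sign = 1.0;
    (void)sign;
    arma::vec z;
    bool tri_ok = true;
    try {
      z = arma::solve(arma::trimatl(L), e);
    } catch (...) { tri_ok = false; }
    if (!tri_ok || !z.is_finite()) {
      conv[i] = 0; ofv_i[i] = R_PosInf; ofv = R_PosInf; continue;
    }
    double quad = arma::dot(z, z);
    double l = n * LOG2PI + ld + quad;
    ofv_i[i] = l;
    ofv += l;
    for (int k = 0; k < q; ++k) eta_out(i, k) = eta[k];
    if (detail) {
      f_hat_out[i] = wrap(fh);
      jac_out[i] = wrap(J);
      indiv_pars(tpv, arma::vec(q, arma::fill::zeros), map, p);
      pred0_out[i] = wrap(conc_sub(t, p, ds, da, dr));
    }
  }

  List out = List::create(_["ofv"] = ofv, _["ofv_i"] = wrap(ofv_i),
                          _["eta"] = wrap(eta_out), _["conv"] = conv);
  if (detail) {
    out["f_hat"] = f_hat_out;
    out["jac"] = jac_out;
    out["pred0"] = pred0_out;
  }
  return out;
}
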