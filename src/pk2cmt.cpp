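// Closed-form two-compartment intravenous-infusion kinetics.
//
// Central-compartment concentration is the superposition, over all infusion
// events, of the standard biexponential infusion / post-infusion solution
// with hybrid rate constants alpha > beta derived from the micro-constants
// k10 = CL/V, k12 = Q/V, k21 = Q/V2.  AUC over arbitrary windows uses the
// exact antiderivative of the same expression, so no quadrature error enters
// exposure metrics.  The unit-bolus central response is
// (A e^{-alpha t} + B e^{-beta t})/V with A = (alpha-k21)/(alpha-beta),
// B = (k21-beta)/(alpha-beta); an infusion is its convolution with a
// constant rate over the infusion duration.

#include <Rcpp.h>
#include "pk2.h"
using namespace Rcpp;

// [[Rcpp::export(name = ".pk2_conc_cpp")]]
NumericVector pk2_conc_cpp(NumericVector times,
                           double V, double V2, double CL, double Q,
                           NumericVector dose_start, NumericVector dose_amt,
                           NumericVector dose_rate) {
  pk2::Macro m = pk2::macro_constants(V, V2, CL, Q);
  int nT = times.size(), nD = dose_start.size();
  NumericVector out(nT);
  for (int i = 0; i < nT; ++i) {
    double cc = 0.0;
    for (int d = 0; d < nD; ++d) {
      double D = dose_amt[d] / dose_rate[d];
      cc += pk2::event_conc(m, dose_rate[d], D, times[i] - dose_start[d]);
    }
    out[i] = cc;
  }
  return out;
}

// [[Rcpp::export(name = ".pk2_auc_cpp")]]
double pk2_auc_cpp(double V, double V2, double CL, double Q,
                   NumericVector dose_start, NumericVector dose_amt,
                   NumericVector dose_rate, double t0, double t1) {
  pk2::Macro m = pk2::macro_constants(V, V2, CL, Q);
  int nD = dose_start.size();
  double auc = 0.0;
  for (int d = 0; d < nD; ++d) {
    double D = dose_amt[d] / dose_rate[d];
    auc += pk2::event_cumauc(m, dose_rate[d], D, t1 - dose_start[d]) -
           pk2::event_cumauc(m, dose_rate[d], D, t0 - dose_start[d]);
  }
  return auc;
}

// Vectorised per-subject AUC for Monte Carlo exposure simulation: each row of
// `pars` is (V, V2, CL, Q) for one simulated subject, dosing is shared.
// [[Rcpp::export(name = ".pk2_auc_many_cpp")]]
NumericVector pk2_auc_many_cpp(NumericMatrix pars,
                               NumericVector dose_start, NumericVector dose_amt,
                               NumericVector dose_rate, double t0, double t1) {
  int n = pars.nrow();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    out[i] = pk2_auc_cpp(pars(i, 0), pars(i, 1), pars(i, 2), pars(i, 3),
                         dose_start, dose_amt, dose_rate, t0, t1);
  }
  return out;
}
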