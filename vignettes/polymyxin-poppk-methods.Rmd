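---
title: "Methods: population pharmacokinetics and dosing simulation of polymyxin B in obese adults"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: population pharmacokinetics and dosing simulation of polymyxin B in obese adults}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polyBpopPK)
```

## The problem

Polymyxin B is a last-line antibiotic for multidrug-resistant Gram-negative
infections with a narrow window between efficacious exposure
(AUC~ss,24h~ 50--100 mg·h/L) and the nephrotoxicity threshold
(AUC~ss,24h~ > 100 mg·h/L). Because it is conventionally dosed by body
weight, obese patients (BMI ≥ 30) are at particular risk of overexposure if
clearance does not scale with weight. This package implements the full
analysis pipeline for that question: a generative two-compartment
population model, synthetic cohorts matching the obese study design,
FOCE-with-interaction estimation with covariate search and diagnostics, and
Monte Carlo evaluation of fixed and weight-based dosing regimens against
exposure and AUC/MIC targets.

## Structural and statistical model

Disposition is a linear two-compartment model parameterised by central
volume $V$ (L), peripheral volume $V_2$ (L), clearance $CL$ (L/h) and
inter-compartmental clearance $Q$ (L/h). With micro-constants
$k_{10} = CL/V$, $k_{12} = Q/V$, $k_{21} = Q/V_2$ and hybrid rate constants
$\alpha > \beta$ (the roots of
$x^2 - (k_{10}+k_{12}+k_{21})x + k_{10}k_{21}$), the unit-bolus central
concentration is $(A e^{-\alpha t} + B e^{-\beta t})/V$ with
$A = (\alpha-k_{21})/(\alpha-\beta)$, $B = (k_{21}-\beta)/(\alpha-\beta)$.
Constant-rate infusions are its convolution with the infusion rate, and an
arbitrary schedule is the superposition over infusion events. Concentration
and AUC are evaluated in closed form (`pk_conc()`, `pk_auc()`); the AUC is
the exact antiderivative, so exposure metrics carry no quadrature error. A
near-repeated-root parameter set ($\alpha \approx \beta$) is handled by a
relative $10^{-6}$ nudge of $k_{21}$, far below every tolerance used
downstream. The tests verify the solver against an independent stiff ODE
integration (deSolve) to within $10^{-6}$ relative.

Between-subject variability is lognormal on $CL$, $V_2$ and $Q$:
$CL_i = \mathrm{tv}CL \cdot e^{\eta_i}$, $\eta_i \sim N(0, \omega^2)$, with
no random effect on $V$ (the sparse-dominated design leaves an $\eta$ on
$V$ with shrinkage above 0.5, the standard removal rule, which the pipeline
reproduces). The default parameter values are the published final-model
estimates: $\mathrm{tv}V = 11.24$ L, $\mathrm{tv}V_2 = 39.70$ L,
$\mathrm{tv}CL = 2.86$ L/h, $\mathrm{tv}Q = 7.36$ L/h,
$\omega^2_{CL} = 0.17$, $\omega^2_{V2} = 1.00$, $\omega^2_Q = 0.43$.

The residual error is proportional: $y = f(1+\varepsilon)$,
$\varepsilon \sim N(0, \sigma^2)$ with $\sigma = 0.24$. The source estimate
is labelled only as a residual standard deviation; we adopt the
proportional (24% CV) reading because an additive 0.24 mg/L would be
implausibly small against the 0.2--10 mg/L assay range, and expose the
additive alternative via `error_model = "additive"`. Simulated
concentrations that would fall below zero (possible when
$\varepsilon < -1$, a <0.02% event at $\sigma = 0.24$) are truncated at
zero and counted.

## Synthetic cohorts

Raw patient data are not available, so the `study_design()` /
`generate_cohort()` pair emulates the study: 26 adults, TBW 75--125 kg with
median near 90 kg (scaled Beta(2,4)), BMI uniform on 30.04--40.35, height
back-computed from TBW and BMI and constrained to 152.4--200 cm (the adult
range consistent with the published IBW spread of 48.8--75.0 kg;
infeasible TBW/BMI pairs are redrawn with a capped retry count), age
discrete-uniform on 18--83, serum creatinine lognormal with median
76 µmol/L truncated to the observed 34--368 range, and a 17:9 male:female
ratio. Only medians and ranges are published, so these marginals are a
design choice, config-exposed, and fixed once.

Dosing follows the empiric bedside policy: loading 100/150/200 mg and
maintenance 50/75/100 mg q12h drawn uniformly per subject, 1-h infusions.
Sampling is anchored at $t = 72$ h (the day-4 trough immediately before the
morning dose): 10 of 26 subjects contribute the rich schedule (0, 1, 1.5,
2, 4, 6, 8 h post-dose) and 16 the two-point TDM schedule (0, 2 h). The
published rich schedules varied between 4 and 7 samples per patient and the
exact per-patient design is unpublished, so a per-subject count sampler is
exposed (`rich_n_sampler`) rather than guessing; the default uses all seven
nominal times. Observations below the LLOQ -- 0.25 mg/L by default, the sum
of the B1 (0.2) and B2 (0.05) lower limits, since the assay sums both
congeners and no combined LLOQ is published -- are flagged and excluded
from estimation, matching the study's exclusion criterion rather than a
censored-likelihood treatment.

What the generator deliberately does not emulate: infection-site and
pathogen covariates (never used in modelling), assay batch effects,
irregular real-world dose timing, and model misspecification -- passing
recovery tests therefore show the estimator is correct under the stated
generative model, not that the published model is correct for real
patients.

## Body-size covariates

`ideal_body_weight()` implements the Devine formula
$[\mathrm{height(cm)}/2.54 - 60] \times 2.3 + 50$ kg (males; 45.5 kg
intercept for females); heights below 152.4 cm give a negative bracket term
and return the formula value with a warning rather than clamping, since the
obese cohort never reaches that region. `adjusted_body_weight()` is
$IBW + 0.4(TBW - IBW)$. `cockcroft_gault()` uses the classic 1976 constant
set $(140-\mathrm{age})\cdot W / (72 \cdot S_{cr}[\mathrm{mg/dL}])$
(females ×0.85) with creatinine converted from µmol/L by 88.4; whether the
original analysis converted units or used a µmol/L-native variant is not
stated, but the choice only rescales CrCL, which was rejected as a
covariate regardless.

## Estimation

`pop_fit()` maximises the FOCE-with-interaction approximate marginal
likelihood. Per subject, the inner problem minimises

$$h(\eta) = \sum_j \left[ \frac{(y_j - f_j(\eta))^2}{\sigma^2 f_j(\eta)^2}
  + \log(\sigma^2 f_j(\eta)^2) \right] + \eta^\top \Omega^{-1} \eta$$

by damped Gauss-Newton (weighted least-squares curvature plus the prior,
Levenberg damping, gradient tolerance $10^{-8}$, warm-started across outer
iterations). At the conditional mode $\hat\eta$ the model is linearised
($J = \partial f/\partial \eta$, central differences) and the subject's
$-2\log L$ is the Gaussian expression with mean $f(\hat\eta) - J\hat\eta$
and covariance $J \Omega J^\top + \sigma^2\,\mathrm{diag}(f(\hat\eta)^2)$
-- the residual variance at the mode is the interaction term. With no
random effects this collapses to the exact extended-least-squares
$-2\log L$, and on one-random-effect problems it agrees with adaptive
quadrature of the true marginal likelihood to well under one OFV unit (both
are tested). Exact Phoenix FOCE ELS internals are proprietary, so agreement
is asserted against the quadrature oracle, not against Phoenix.

The outer problem optimises $\log$-transformed $\theta$, $\omega^2$ and
$\sigma$ (plus any covariate coefficients, untransformed) by quasi-Newton
(`nlminb`) followed by alternating Nelder-Mead polish and quasi-Newton
restarts until a full cycle improves the OFV by less than 0.01. Standard
errors come from the central-difference Hessian of the OFV at the optimum
($\mathrm{cov} = 2H^{-1}$), reported as SE, RSE% and normal-theory 95% CI;
a singular Hessian drops the SEs with a warning. Starting values default to
a naive-pooled heuristic (clearance from the pooled mean steady-state
concentration, central volume from the pooled peak-trough swing). Empirical
Bayes etas are the conditional modes at the optimum and shrinkage is
$1 - \mathrm{SD}(\hat\eta)/\omega$, with the >0.5 rule exposed as the
model-reduction advisory.

Covariate search (`stepwise_covariates()`) is forward addition while the
best candidate drops the OFV by more than 6.63 ($p = 0.01$, 1 df), then
backward elimination of terms whose removal raises the OFV by at most 10.83
($p = 0.001$). The functional forms are the dominant pharmacometric
convention (unstated in the source): power models normalised to the cohort
median for continuous covariates, an exponential proportional shift for
sex. Ties within 0.01 OFV break to the fewest added parameters, then
alphabetically, for determinism. The pipeline order is structural model →
IIV pruning by the shrinkage rule → covariate search, following the
narrative order of the source analysis. The nonparametric bootstrap
resamples subjects with replacement, refits each replicate warm-started
from the point estimate, and reports replicate medians, SDs and percentile
CIs; replicates that fail are counted and more than 50% failures aborts.

## Diagnostics

`pop_cwres()` returns FOCE-linearised conditional weighted residuals
(Cholesky decorrelation by the subject-level linearised covariance), which
are approximately $N(0,1)$ under a correct model; the tests verify the
calibration on self-simulated data and that a structurally misspecified
(near-one-compartment) model produces a strong residual-time trend.
`pop_vpc()` is a prediction-corrected VPC: observed and simulated
concentrations are rescaled by (bin median population prediction)/(own
population prediction), and the 5th/50th/95th percentiles of the corrected
observations are compared with their 90% simulation bands. Binning defaults
to the nominal protocol times (the design is nominal-time); bins with fewer
than two observations merge into a neighbour with a warning. Percentiles
use the Hazen convention (`type = 5`) throughout -- stated because
percentile dialects shift band edges.

## Dosing simulation

`simulate_exposures()` draws individual parameters, builds the simulation
regimen (loading at $t = 0$, maintenance q12h from $t = 12$, all infusions
at 50 mg/h, so a 300 mg load runs 6 h) and computes two residual-error-free
exposure metrics per subject: AUC over the first 24 h (for AUC/MIC targets)
and the day-4 AUC over [72, 96) h. Day-4 integration, not the analytic
steady-state shortcut $\mathrm{dose}_{daily}/CL$, is the default: with
$\omega^2_{V2} = 1.00$ a heavy tail of subjects has terminal half-lives of
days and is materially short of steady state on day 4, which is what brings
the toxicity probabilities down to the published values (the shortcut is
retained as `mode = "steady_state"` and as the closed-form lognormal
cross-check `target_prob_analytic()`, which reproduces the 200 mg/day
target probability of 0.599 without any simulation). Exposures use
individual predictions without residual error, standard exposure-simulation
practice. Target classification is inclusive on [50, 100] and strict above
100; ties are measure-zero under the continuous model.

The studied regimen set (`table3_regimens()`) is five fixed regimens
(50--150 mg q12h maintenance with double-dose loading per the methods text;
the report table's row labels print 200 mg loading for the two high-dose
arms instead, and that variant is selectable) plus 2.5 mg/kg loading with
1.25 or 1.5 mg/kg maintenance at the 10th/50th/90th percentiles of TBW,
ABW and IBW. Weight-based doses are not rounded to vial sizes (no rounding
rule is published). PTA is the fraction of subjects with total-drug
AUC$_{0-24}$/MIC > 50 over MIC 0.125--8 mg/L, with the ≥90% adequacy flag.
One published PTA cell (19.9% at MIC 0.5 for the highest fixed arm)
violates MIC monotonicity against its neighbours and is treated as a
typographical artefact; the package's monotonicity invariant is tested
instead.

## Numerical choices and problem sizes

Simulation sizes follow the source conventions at full scale (1,000
Monte Carlo subjects per regimen; 1,000 VPC replicates supported). The
packaged analysis scripts and tests run the estimation-heavy steps at desk
scale as their own design choice: 20-seed recovery studies of the
26-subject design, 200 bootstrap replicates, 300--500 VPC replicates.
Concentration evaluation and the FOCE inner problem are implemented in
C++ (Rcpp/RcppArmadillo), the layer at which comparable NLME engines work.

Known limitations, all visible in the reported tables rather than hidden:
the day-4-only sampling window identifies $V_2$ and its variance weakly
(large RSE on $\mathrm{tv}V_2$, downward-biased $\omega^2_{V2}$, and a
mild upward small-sample bias of a few percent in recovered clearance --
the 20-seed recovery median sits about 5--8% above the generating value,
within the tolerance the acceptance checks state); bootstrap replicates of
sparse-heavy resamples occasionally land in a large-$V_2$/low-$CL$ mode,
widening the percentile CI relative to the published interval; and BLQ
handling is exclusion, not censored likelihood, by design fidelity to the
source analysis.
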