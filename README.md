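# polyBpopPK

Population pharmacokinetics and dosing simulation of polymyxin B in obese
adults.

Polymyxin B is a last-line antibiotic against multidrug-resistant
Gram-negative bacteria with a narrow exposure window: a day-4 24-h area
under the concentration-time curve (AUC_ss,24h) of 50-100 mg·h/L is the
efficacy target, and AUC_ss,24h > 100 mg·h/L predicts nephrotoxicity.
Because the drug is dosed by body weight, obese patients (BMI ≥ 30) risk
overexposure if clearance does not scale with weight. This package is the
complete analysis pipeline for that question, aimed at pharmacometricians
and infectious-disease modellers:

- **PK engine** — closed-form two-compartment intravenous-infusion
  concentration `C(t)` and exact AUC under arbitrary infusion schedules
  (`pk_conc()`, `pk_auc()`), with micro-constants k10 = CL/V, k12 = Q/V,
  k21 = Q/V2 and hybrid rate constants α > β.
- **Generative population model** — typical values with diagonal lognormal
  inter-individual variability (CL_i = tvCL·e^η, η ~ N(0, ω²)) and
  proportional residual error (`population_model()`); defaults are the
  published final-model estimates (tvV 11.24 L, tvV2 39.70 L, tvCL
  2.86 L/h, tvQ 7.36 L/h; ω²CL 0.17, ω²V2 1.00, ω²Q 0.43; σ 0.24).
- **Synthetic cohorts** — 26 obese adults with covariates drawn to the
  published medians/ranges, empiric dosing (100-200 mg loading, 50-100 mg
  q12h, 1-h infusions), day-4 rich (7-point) or sparse (2-point) sampling,
  and LLOQ censoring (`study_design()`, `generate_cohort()`).
- **Estimation** — FOCE-with-interaction nonlinear mixed-effects fitting
  (`pop_fit()`), empirical-Bayes etas and shrinkage, stepwise covariate
  selection at ΔOFV > 6.63 forward / > 10.83 backward
  (`stepwise_covariates()`), nonparametric bootstrap (`pop_bootstrap()`).
- **Diagnostics** — conditional weighted residuals (`pop_cwres()`) and a
  prediction-corrected visual predictive check (`pop_vpc()`).
- **Dosing simulation** — Monte Carlo exposure and probability-of-target-
  attainment tables for five fixed and eighteen bodyweight-based regimens
  (`simulate_exposures()`, `exposure_probabilities()`, `pta()`,
  `table3_report()`), plus a closed-form lognormal cross-check
  (`target_prob_analytic()`).

## Worked example

```r
library(polyBpopPK)

model <- population_model()           # published final-model parameters

# Monte Carlo evaluation of the fixed 200 mg + 100 mg q12h regimen
spec <- regimen_spec(loading_mg = 200, maintenance_mg = 100)
ex   <- simulate_exposures(model, spec, n = 1000, seed = 1)
exposure_probabilities(ex)[, c("p_target", "p_toxicity", "auc_median")]
#>   p_target p_toxicity auc_median
#> 1     60.6       14.5   65.11489
pta(ex)
#>     mic   pta adequate
#> 1 0.125 100.0     TRUE
#> 2 0.250 100.0     TRUE
#> 3 0.500  98.9     TRUE
#> 4 1.000  75.4    FALSE
#> 5 2.000  12.6    FALSE
#> 6 4.000   0.0    FALSE
#> 7 8.000   0.0    FALSE
```

About 60% of simulated subjects hit the 50-100 mg·h/L day-4 exposure
window under 100 mg q12h, with a 14% toxicity risk; the regimen attains
the AUC/MIC > 50 target in ≥ 90% of subjects only for MIC ≤ 0.5 mg/L.

```r
# fit the model back from a synthetic cohort of the study design
cohort <- generate_cohort(study_design(), model, seed = 2)
fit <- pop_fit(cohort)
print(fit)
#> FOCE fit: 26 subjects, 101 observations, OFV = 242.159
#>   theta : V=10.87  V2=35.16  CL=3.164  Q=5.672
#>   omega2: CL=0.218  V2=0.4297  Q=0.2957
#>   sigma : 0.2286
#>   shrinkage: CL=2.9%  V2=63.1%  Q=32.9%
```

A single 26-subject cohort is a small sample, so individual fits scatter
around the generating values (and the day-4-only sampling window identifies
V2 weakly — see the methods vignette); the acceptance study below fits 20
seeds and recovers tvCL at the median.

The numbered scripts under `analysis/` run the full workflow end to end —
cohort generation, estimation with the η-on-V shrinkage decision, covariate
search, bootstrap, GOF/pc-VPC, and the 23-regimen dosing table — writing
tables and figures to `results/`.

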