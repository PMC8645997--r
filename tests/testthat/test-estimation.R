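test_that("with no random effects the OFV is the exact proportional-error -2LL", {
  m <- population_model()
  dat <- build_dataset(m, n = 3, times = c(73, 74, 76), seed = 21)
  obs <- dat[dat$EVID == 0, ]
  dose <- dat[dat$EVID == 1, ]
  # direct Gaussian density oracle
  direct <- 0
  for (id in unique(obs$ID)) {
    o <- obs[obs$ID == id, ]; dd <- dose[dose$ID == id, ]
    reg <- regimen_from_events(data.frame(start = dd$TIME, amount = dd$AMT,
                                          rate = dd$RATE))
    f <- pk_conc(m$theta, reg, o$TIME)
    direct <- direct - 2 * sum(dnorm(o$DV, f, 0.24 * f, log = TRUE))
  }
  ofv <- pop_ofv(dat, m$theta, omega2 = setNames(numeric(0), character(0)),
                 sigma = 0.24)
  expect_equal(as.numeric(ofv), direct, tolerance = 1e-8)
})

test_that("FOCE OFV tracks the adaptive-quadrature marginal likelihood", {
  m <- population_model(omega2 = c(CL = 0.17), sigma = 0.15)
  for (s in c(7, 8)) {
    dat <- build_dataset(m, n = 2, times = c(72, 73, 76), seed = s)
    ofv <- as.numeric(pop_ofv(dat, m$theta, m$omega2, m$sigma))
    expect_equal(ofv, quadrature_m2ll(dat, m), tolerance = 1 / abs(ofv),
                 label = sprintf("FOCE OFV (seed %d)", s))
  }
})

test_that("OFV is invariant to subject ordering", {
  m <- population_model()
  dat <- build_dataset(m, n = 6, times = c(72, 74, 78), seed = 31)
  perm <- dat
  perm$ID <- max(perm$ID) + 1 - perm$ID # reverse subject labels
  perm <- perm[order(perm$ID, perm$TIME, -perm$EVID), ]
  class(perm) <- class(dat)
  a <- as.numeric(pop_ofv(dat, m$theta, m$omega2, m$sigma))
  b <- as.numeric(pop_ofv(perm, m$theta, m$omega2, m$sigma))
  expect_equal(a, b, tolerance = 1e-10)
})

test_that("noise-free fixed-effects data identify theta almost exactly", {
  m <- population_model(omega2 = c(CL = 1e-12, V2 = 1e-12, Q = 1e-12),
                        sigma = 1e-5)
  dat <- build_dataset(m, n = 6, times = INFORMATIVE_TIMES, seed = 41)
  fit <- pop_fit(dat, init = list(theta = c(V = 9, V2 = 30, CL = 2.2, Q = 5),
                                  omega2 = c(CL = 0.05, V2 = 0.05, Q = 0.05),
                                  sigma = 0.05),
                 settings = list(compute_se = FALSE))
  expect_equal(unname(fit$theta), c(11.24, 39.70, 2.86, 7.36),
               tolerance = 1e-3)
})

test_that("the generative model is recovered from an informative design", {
  m <- population_model()
  dat <- build_dataset(m, n = 60, times = INFORMATIVE_TIMES, seed = 9)
  fit <- pop_fit(dat, settings = list(compute_se = FALSE))
  expect_equal(unname(fit$theta), c(11.24, 39.70, 2.86, 7.36), tolerance = 0.12)
  expect_equal(unname(fit$omega2[c("CL", "V2", "Q")]), c(0.17, 1.00, 0.43),
               tolerance = 0.35)
  expect_equal(fit$sigma, 0.24, tolerance = 0.1)
  expect_true(fit$converged)
  # nested-model consistency: pinning the V2 random effect to (near) zero
  # can never beat the free model
  pinned <- pop_ofv(dat, fit$theta,
                    omega2 = c(CL = fit$omega2[["CL"]], V2 = 1e-10,
                               Q = fit$omega2[["Q"]]),
                    sigma = fit$sigma)
  expect_gt(as.numeric(pinned), fit$ofv - 0.1)
})

test_that("standard errors and shrinkage are reported in the parameter table", {
  m <- population_model()
  dat <- build_dataset(m, n = 30, times = INFORMATIVE_TIMES, seed = 13)
  fit <- pop_fit(dat)
  tab <- fit$parameter_table
  expect_s3_class(tab, "data.frame")
  expect_true(all(c("estimate", "se", "rse_pct", "ci_lo", "ci_hi",
                    "shrinkage_pct") %in% names(tab)))
  expect_true(all(is.finite(tab$se)))
  expect_true(all(tab$ci_lo < tab$ci_hi))
  expect_true(all(is.finite(tab$shrinkage_pct[grepl("omega2", tab$parameter)])))
})

test_that("eta shrinkage has its closed-form limits", {
  expect_equal(unname(eta_shrinkage(matrix(0, 10, 1), c(CL = 0.2))), 1)
  set.seed(1)
  e <- rnorm(4000, 0, sqrt(0.2))
  expect_equal(unname(eta_shrinkage(matrix(e, ncol = 1), c(CL = 0.2))), 0,
               tolerance = 0.05)
  expect_true(is.na(eta_shrinkage(matrix(e, ncol = 1), c(CL = 0))))
  expect_error(eta_shrinkage(matrix(0, 1, 1), c(CL = 0.2)), "2 subjects")
})

test_that("a sparse two-point design shrinks the V random effect", {
  m <- population_model()
  dat <- build_dataset(m, n = 26, times = c(72, 74), seed = 17)
  fit <- pop_fit(dat, init = list(theta = m$theta,
                                  omega2 = c(V = 0.2, CL = 0.17, V2 = 1, Q = 0.43),
                                  sigma = 0.24),
                 random_effects = c("V", "CL", "V2", "Q"),
                 settings = list(compute_se = FALSE, polish = FALSE))
  expect_gt(fit$shrinkage[["V"]], 0.5)
})

test_that("stepwise search with no candidates returns the base fit", {
  m <- population_model()
  dat <- suppressWarnings(generate_cohort(study_design(n_subjects = 12), m, seed = 3))
  base <- pop_fit(dat, init = m, settings = list(compute_se = FALSE, polish = FALSE))
  out <- stepwise_covariates(dat, base, candidates = list())
  expect_length(out$final_terms, 0)
  expect_equal(out$final_fit$ofv, base$ofv)
  expect_equal(nrow(out$log), 0)
})

test_that("a strong simulated clearance-covariate effect is selected", {
  m <- population_model(omega2 = c(CL = 0.05, V2 = 0.3, Q = 0.2))
  set.seed(55)
  cov <- polyBpopPK:::draw_covariates(40, study_design()$covariates)
  mult <- (cov$CRCL_TBW / median(cov$CRCL_TBW))^0.75
  dat <- build_dataset(m, n = 40, times = c(72, 73, 74, 76, 80), seed = 55,
                       cl_multiplier = mult, covariates = cov)
  base <- pop_fit(dat, init = m, settings = list(compute_se = FALSE, polish = FALSE))
  cand <- list(covariate_term("CL", "CRCL_TBW"), covariate_term("CL", "AGE"),
               covariate_term("CL", "SEX"))
  out <- stepwise_covariates(dat, base, candidates = cand)
  labs <- vapply(out$final_terms, function(tm) tm$cov, "")
  expect_true("CRCL_TBW" %in% labs)
  added <- out$log[out$log$decision == "added" & out$log$term == "CRCL_TBW~CL", ]
  expect_gt(added$dofv[1], 6.63)
})

test_that("the bootstrap is seeded, summarised and failure-aware", {
  m <- population_model()
  dat <- build_dataset(m, n = 12, times = c(72, 73, 74, 76, 80), seed = 77)
  fit <- pop_fit(dat, init = m, settings = list(compute_se = FALSE, polish = FALSE))
  b1 <- pop_bootstrap(dat, fit, n_resamples = 8, seed = 5)
  b2 <- pop_bootstrap(dat, fit, n_resamples = 8, seed = 5)
  expect_identical(b1$summary, b2$summary)
  expect_true(all(b1$summary$ci_lo <= b1$summary$median))
  expect_true(all(b1$summary$median <= b1$summary$ci_hi))
  expect_equal(b1$convergence_fraction, 1 - b1$n_failed / 8)
})
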