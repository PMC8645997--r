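test_that("CWRES reduces to scaled residuals without random effects", {
  m <- population_model(omega2 = c(CL = 1e-12), sigma = 0.24)
  dat <- build_dataset(m, n = 4, times = c(72, 74, 78), seed = 51)
  fit0 <- fake_fit(population_model(), n_subjects = 4, random_effects = character(0))
  fit0$omega2 <- setNames(numeric(0), character(0))
  fit0$eta <- matrix(0, 4, 0)
  res <- pop_cwres(dat, fit0)
  expect_equal(res$CWRES, (res$DV - res$PRED) / (0.24 * res$PRED),
               tolerance = 1e-10)
  expect_equal(res$IPRED, res$PRED)
})

test_that("CWRES is calibrated near N(0,1) under the true model", {
  m <- population_model()
  dat <- build_dataset(m, n = 150, times = c(72, 73, 74, 76, 78, 80, 82),
                       seed = 53)
  fit <- fake_fit(m, n_subjects = 150)
  res <- pop_cwres(dat, fit)
  expect_gt(nrow(res), 1000)
  expect_lt(abs(mean(res$CWRES)), 0.1)
  expect_lt(abs(sd(res$CWRES) - 1), 0.15)
})

test_that("CWRES detects structural misspecification as a time trend", {
  m <- population_model()
  dat <- build_dataset(m, n = 40, times = c(72, 73, 74, 76, 80), seed = 57)
  # a near-one-compartment model cannot track the distribution phase of
  # two-compartment data: residuals acquire a time trend and inflate
  wrong <- population_model(theta = c(V = 30, V2 = 0.1, CL = 2.86, Q = 0.01),
                            omega2 = c(CL = 0.17), sigma = 0.24)
  res <- pop_cwres(dat, fake_fit(wrong, 40, random_effects = "CL"))
  trend <- summary(lm(CWRES ~ TIME, data = res))
  expect_lt(coef(trend)[2, 4], 0.01)
  expect_gt(sd(res$CWRES), 1.3)
})

test_that("prediction correction is exact for proportional dose differences", {
  m <- population_model()
  t_obs <- c(72, 74, 78)
  # homogeneous dosing: the population prediction is constant within each
  # bin, so corrected percentiles equal raw percentiles
  d1 <- build_dataset(m, n = 12, times = t_obs, loading = 100, maintenance = 50,
                      seed = 61)
  v1 <- pop_vpc(d1, m, n_replicates = 100, seed = 1)
  obs1 <- d1[d1$EVID == 0, ]
  raw <- unlist(lapply(t_obs, function(tt)
    quantile(obs1$DV[obs1$TIME == tt], c(0.05, 0.5, 0.95), type = 5,
             names = FALSE)))
  expect_equal(v1$observed[order(v1$bin_time, v1$percentile)], raw,
               tolerance = 1e-10)
  # a second group identical except for a doubled dose (same seed, so the
  # same etas and residuals, scaled by linearity): correction collapses both
  # groups onto one profile, a fixed multiple of the single-group run
  d2 <- build_dataset(m, n = 12, times = t_obs, loading = 200, maintenance = 100,
                      seed = 61)
  d2$ID <- d2$ID + 12L
  dat <- rbind(d1, d2)
  class(dat) <- class(d1)
  v <- pop_vpc(dat, m, n_replicates = 100, seed = 1)
  # corrected values of the two groups coincide pairwise, so the merged
  # median is the single-group median rescaled by the pooled bin median
  med <- v$percentile == 50
  expect_equal(v$observed[med], 1.5 * v1$observed[med], tolerance = 1e-8)
})

test_that("VPC bands are ordered and cover self-simulated data", {
  m <- population_model()
  dat <- suppressWarnings(generate_cohort(study_design(), m, seed = 65))
  v <- pop_vpc(dat, m, n_replicates = 300, seed = 2)
  expect_true(all(v$sim_lo <= v$sim_med & v$sim_med <= v$sim_hi))
  med <- v[v$percentile == 50, ]
  covered <- mean(med$observed >= med$sim_lo & med$observed <= med$sim_hi)
  expect_gte(covered, 0.8)
  expect_error(pop_vpc(dat, m, n_replicates = 50), ">= 100")
})

test_that("a doubled clearance pushes the observed median outside the band", {
  m <- population_model()
  dat <- build_dataset(m, n = 26, times = c(72, 73, 74, 76, 78, 80), seed = 67)
  wrong <- population_model(theta = c(V = 11.24, V2 = 39.70, CL = 5.72, Q = 7.36))
  v <- pop_vpc(dat, wrong, n_replicates = 200, seed = 3)
  med <- v[v$percentile == 50, ]
  expect_gt(sum(med$observed > med$sim_hi), nrow(med) / 2)
})
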