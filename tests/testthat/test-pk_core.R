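test_that("empty regimen and basic limits behave", {
  p <- pk_params(11.24, 39.70, 2.86, 7.36)
  empty <- regimen_from_events(data.frame(start = numeric(0),
                                          amount = numeric(0),
                                          rate = numeric(0)))
  expect_equal(pk_conc(p, empty, c(0, 1, 50)), c(0, 0, 0))
  expect_equal(pk_auc(p, empty, 0, 24), 0)
  # near-bolus, near-one-compartment limit: C(0+) ~ Dose/V
  p1 <- pk_params(11.24, 39.70, 2.86, 1e-8)
  fast <- regimen_from_events(data.frame(start = 0, amount = 100, rate = 1e4))
  expect_equal(pk_conc(p1, fast, 0.01), 100 / 11.24, tolerance = 5e-3)
  expect_error(pk_conc(p, empty, -1), "times")
  expect_error(pk_params(1, 1, -1, 1), "finite and > 0")
})

test_that("closed form agrees with a stiff ODE oracle on random problems", {
  skip_if_not_installed("deSolve")
  set.seed(11)
  worst_conc <- 0; worst_auc <- 0
  for (i in 1:40) {
    p <- pk_params(runif(1, 3, 40), runif(1, 5, 120),
                   runif(1, 0.5, 8), runif(1, 0.5, 15))
    loading <- runif(1, 50, 300)
    maint <- runif(1, 25, 150)
    reg <- dosing_regimen(loading, maint, infusion_rate = runif(1, 25, 100),
                          horizon = 96)
    times <- sort(runif(6, 0.5, 90))
    oracle <- ode_conc_auc(p, reg, times)
    conc <- pk_conc(p, reg, times)
    worst_conc <- max(worst_conc, max(abs(conc - oracle$conc) / oracle$conc))
    auc <- vapply(times, function(tt) pk_auc(p, reg, 0, tt), 0)
    worst_auc <- max(worst_auc, max(abs(auc - oracle$cum_auc) / oracle$cum_auc))
  }
  expect_lt(worst_conc, 1e-6)
  expect_lt(worst_auc, 1e-5)
})

test_that("AUC obeys the Dose/CL identities", {
  p <- pk_params(11.24, 39.70, 2.86, 7.36)
  single <- dosing_regimen(100, NULL, infusion_duration = 1)
  expect_equal(pk_auc(p, single, 0, 5e4), 100 / 2.86, tolerance = 1e-6)
  # steady state 100 mg q12h: daily dose / CL over any 24-h window
  ss <- dosing_regimen(NULL, 100, infusion_rate = 50, horizon = 12 * 400)
  expect_equal(pk_auc(p, ss, 12 * 350, 12 * 350 + 24), 200 / 2.86,
               tolerance = 1e-6)
})

test_that("AUC is additive over windows and linear in dose", {
  set.seed(3)
  for (i in 1:10) {
    p <- pk_params(runif(1, 5, 30), runif(1, 10, 80),
                   runif(1, 1, 6), runif(1, 1, 12))
    reg <- dosing_regimen(200, 100, infusion_rate = 50, horizon = 96)
    t0 <- runif(1, 0, 40); t1 <- t0 + runif(1, 10, 50); tm <- runif(1, t0, t1)
    full <- pk_auc(p, reg, t0, t1)
    expect_equal(pk_auc(p, reg, t0, tm) + pk_auc(p, reg, tm, t1), full,
                 tolerance = 1e-10)
    dbl <- regimen_from_events(data.frame(start = reg$start,
                                          amount = 2 * reg$amount,
                                          rate = 2 * reg$rate))
    expect_equal(pk_auc(p, dbl, t0, t1), 2 * full, tolerance = 1e-10)
    tt <- runif(3, 0, 90)
    expect_equal(pk_conc(p, dbl, tt), 2 * pk_conc(p, reg, tt),
                 tolerance = 1e-10)
  }
})

test_that("log-concentration decays at the terminal rate beta", {
  p <- pk_params(11.24, 39.70, 2.86, 7.36)
  k10 <- 2.86 / 11.24; k12 <- 7.36 / 11.24; k21 <- 7.36 / 39.70
  s <- k10 + k12 + k21
  beta <- (s - sqrt(s^2 - 4 * k10 * k21)) / 2
  reg <- dosing_regimen(100, NULL, infusion_duration = 1)
  tt <- seq(1 + 3 / beta, 1 + 5 / beta, length.out = 20)
  slope <- coef(lm(log(pk_conc(p, reg, tt)) ~ tt))[[2]]
  expect_equal(slope, -beta, tolerance = 1e-3)
})

test_that("exposure windows are the documented 24-h spans", {
  expect_equal(steady_state_window("day4"), c(72, 96))
  expect_equal(steady_state_window("first24"), c(0, 24))
  expect_equal(diff(steady_state_window("day4")), 24)
})
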