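# Independent oracles and small dataset builders shared across tests.

table2_model <- function(...) population_model(...)

# Stiff-integrator oracle for the two-compartment infusion system:
# dA1/dt = in(t) - (k10 + k12) A1 + k21 A2 ; dA2/dt = k12 A1 - k21 A2,
# C = A1/V, with a third state accumulating the AUC. Integrated piecewise
# between infusion on/off boundaries so the forcing stays smooth.
ode_conc_auc <- function(params, regimen, times) {
  p <- unlist(params)[c("V", "V2", "CL", "Q")]
  k10 <- p[["CL"]] / p[["V"]]; k12 <- p[["Q"]] / p[["V"]]
  k21 <- p[["Q"]] / p[["V2"]]
  bounds <- sort(unique(c(0, regimen$start, regimen$start + regimen$amount / regimen$rate,
                          times)))
  bounds <- bounds[bounds <= max(times) + 1e-12]
  deriv <- function(t, y, parms) {
    rate_in <- sum(regimen$rate[t >= regimen$start - 1e-12 &
                                t < regimen$start + regimen$amount / regimen$rate - 1e-12])
    list(c(rate_in - (k10 + k12) * y[1] + k21 * y[2],
           k12 * y[1] - k21 * y[2],
           y[1] / p[["V"]]))
  }
  state <- c(A1 = 0, A2 = 0, AUC = 0)
  out <- matrix(NA_real_, length(bounds), 3)
  out[1, ] <- state
  for (i in seq_len(length(bounds) - 1)) {
    seg <- deSolve::lsoda(state, c(bounds[i], bounds[i + 1]), deriv, NULL,
                          rtol = 1e-11, atol = 1e-12)
    state <- unname(seg[nrow(seg), -1])
    out[i + 1, ] <- state
  }
  idx <- match(times, bounds)
  data.frame(time = times, conc = out[idx, 1] / p[["V"]], cum_auc = out[idx, 3])
}

# Adaptive-quadrature -2 log marginal likelihood for a one-random-effect
# (eta on CL) proportional-error model.
quadrature_m2ll <- function(dataset, model) {
  obs <- dataset[dataset$EVID == 0 & dataset$MDV == 0, ]
  dose <- dataset[dataset$EVID == 1, ]
  total <- 0
  for (id in unique(obs$ID)) {
    o <- obs[obs$ID == id, ]
    dd <- dose[dose$ID == id, ]
    reg <- regimen_from_events(data.frame(start = dd$TIME, amount = dd$AMT,
                                          rate = dd$RATE))
    integrand <- Vectorize(function(eta) {
      p <- model$theta
      p[["CL"]] <- p[["CL"]] * exp(eta)
      f <- pk_conc(p, reg, o$TIME)
      exp(sum(dnorm(o$DV, f, model$sigma * f, log = TRUE)) +
            dnorm(eta, 0, sqrt(model$omega2[["CL"]]), log = TRUE))
    })
    L <- integrate(integrand, -5, 5, rel.tol = 1e-10)$value
    total <- total - 2 * log(L)
  }
  total
}

# Hand-built long dataset: shared regimen, per-subject parameters drawn from
# `model` (optionally scaled), observations at `times` with residual error.
build_dataset <- function(model, n, times, loading = 100, maintenance = 50,
                          seed = 1, cl_multiplier = NULL, covariates = NULL) {
  set.seed(seed)
  pars <- sample_individuals(model, n)
  if (!is.null(cl_multiplier)) pars$CL <- pars$CL * cl_multiplier
  reg <- dosing_regimen(loading, maintenance, infusion_duration = 1, horizon = 96)
  rows <- lapply(seq_len(n), function(i) {
    dv <- simulate_observations(pars[i, ], reg, times, sigma = model$sigma)
    rbind(data.frame(ID = i, TIME = reg$start, AMT = reg$amount, RATE = reg$rate,
                     EVID = 1L, DV = NA_real_, MDV = 1L, BLQ = 0L),
          data.frame(ID = i, TIME = times, AMT = NA_real_, RATE = NA_real_,
                     EVID = 0L, DV = as.numeric(dv), MDV = 0L, BLQ = 0L))
  })
  dat <- do.call(rbind, rows)
  if (!is.null(covariates)) dat <- merge(dat, covariates, by = "ID", sort = FALSE)
  dat <- dat[order(dat$ID, dat$TIME, -dat$EVID), ]
  rownames(dat) <- NULL
  class(dat) <- c("pk_dataset", "data.frame")
  attr(dat, "true_pars") <- pars
  dat
}

# informative multi-day sampling times used for recovery checks
INFORMATIVE_TIMES <- c(1, 2, 4, 8, 12, 13, 16, 24, 48, 72, 73, 76, 80, 88)

fake_fit <- function(model, n_subjects, random_effects = names(model$omega2)) {
  structure(list(theta = model$theta, omega2 = model$omega2[random_effects],
                 sigma = model$sigma, cov_model = NULL, coefs = numeric(0),
                 random_effects = random_effects,
                 eta = matrix(0, n_subjects, length(random_effects),
                              dimnames = list(NULL, random_effects))),
            class = "pop_fit")
}
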