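# Nonlinear mixed-effects estimation: FOCE-with-interaction objective,
# maximum-likelihood fit, EBE shrinkage, stepwise covariate search and the
# nonparametric bootstrap. The per-subject inner problem and likelihood
# assembly live in src/foce.cpp; this file owns the outer optimisation.

PARAM_NAMES <- c("V", "V2", "CL", "Q")

# Split a long pk_dataset into the per-subject pieces the C++ engine wants.
# BLQ / MDV observation rows are dropped here (the study excluded them).
prepare_nlme_data <- function(dataset) {
  obs <- dataset[dataset$EVID == 0 & dataset$MDV == 0 & dataset$BLQ == 0, ]
  dose <- dataset[dataset$EVID == 1, ]
  ids <- sort(unique(dataset$ID))
  keep <- ids %in% obs$ID
  if (!all(keep)) ids <- ids[keep] # subjects with no usable observations drop out
  split_by <- function(df, col) lapply(ids, function(i) df[df$ID == i, col])
  cov_cols <- intersect(c("SEX", "AGE", "HT", "TBW", "SCR", "SOFA", "GFR", "BMI",
                          "IBW", "ABW", "CRCL_TBW", "CRCL_ABW", "CRCL_IBW"),
                        names(dataset))
  covdf <- unique(dataset[dataset$ID %in% ids, c("ID", cov_cols), drop = FALSE])
  covdf <- covdf[match(ids, covdf$ID), , drop = FALSE]
  list(ids = ids, n = length(ids),
       obs_t = split_by(obs, "TIME"), obs_y = split_by(obs, "DV"),
       dose_start = split_by(dose, "TIME"), dose_amt = split_by(dose, "AMT"),
       dose_rate = split_by(dose, "RATE"), cov = covdf)
}

#' Define a covariate-parameter relationship
#'
#' Continuous covariates enter as power models normalised to a reference
#' (the cohort median): `typical * (cov/ref)^coef`. Binary covariates (SEX)
#' enter as an exponential proportional shift `typical * exp(coef * cov)`.
#'
#' @param param structural parameter name (`"V"`, `"V2"`, `"CL"`, `"Q"`).
#' @param cov covariate column name in the dataset.
#' @param type `"power"` or `"exponential"`; default picks `"exponential"`
#'   for SEX and `"power"` otherwise.
#' @param ref reference value for power models; `NULL` means the cohort
#'   median, resolved at fit time.
#' @return a `covariate_term` list.
#' @export
covariate_term <- function(param, cov, type = NULL, ref = NULL) {
  stopifnot(param %in% PARAM_NAMES)
  if (is.null(type)) type <- if (cov == "SEX") "exponential" else "power"
  structure(list(param = param, cov = cov, type = type, ref = ref),
            class = "covariate_term")
}

resolve_refs <- function(cov_model, covdf) {
  lapply(cov_model, function(tm) {
    if (tm$type == "power" && is.null(tm$ref)) tm$ref <- median(covdf[[tm$cov]])
    tm
  })
}

# subject-level typical parameter matrix with covariate effects folded in
tp_matrix <- function(theta, covdf, cov_model = NULL, coefs = numeric(0)) {
  n <- nrow(covdf)
  tp <- matrix(rep(theta[PARAM_NAMES], each = n), nrow = n,
               dimnames = list(NULL, PARAM_NAMES))
  for (j in seq_along(cov_model)) {
    tm <- cov_model[[j]]
    x <- covdf[[tm$cov]]
    tp[, tm$param] <- tp[, tm$param] *
      if (tm$type == "power") (x / tm$ref)^coefs[j] else exp(coefs[j] * x)
  }
  tp
}

#' FOCE objective function value
#'
#' -2 times the FOCE-with-interaction approximate marginal log-likelihood of
#' the dataset under the given population parameters: per subject the
#' conditional mode of the random effects is found, the model is linearised
#' there, and the Gaussian marginal is evaluated with the residual variance
#' taken at the mode. With no random effects this is the exact
#' proportional-error (extended least squares) -2 log-likelihood.
#'
#' @param dataset a `pk_dataset` (BLQ/MDV rows are excluded).
#' @param theta named typical values (V, V2, CL, Q).
#' @param omega2 named IIV variances (subset of the parameters), all > 0;
#'   an empty vector means no random effects.
#' @param sigma residual proportional SD, > 0.
#' @param cov_model optional list of [covariate_term()]s.
#' @param coefs covariate coefficients, one per term.
#' @return the OFV (numeric scalar) with attribute `"eta"` (conditional
#'   modes) and `"conv"`.
#' @export
pop_ofv <- function(dataset, theta, omega2 = c(CL = 0.17, V2 = 1.0, Q = 0.43),
                    sigma = 0.24, cov_model = NULL, coefs = numeric(0)) {
  dp <- prepare_nlme_data(dataset)
  cov_model <- resolve_refs(cov_model, dp$cov)
  eta0 <- matrix(0, dp$n, length(omega2))
  res <- foce_eval(dp, theta, omega2, sigma, cov_model, coefs, eta0)
  structure(res$ofv, eta = res$eta, conv = res$conv)
}

foce_eval <- function(dp, theta, omega2, sigma, cov_model, coefs, eta_start,
                      detail = FALSE) {
  tp <- tp_matrix(theta, dp$cov, cov_model, coefs)
  eta_map <- match(names(omega2), PARAM_NAMES) - 1L
  .foce_ofv_cpp(dp$obs_t, dp$obs_y, dp$dose_start, dp$dose_amt, dp$dose_rate,
                tp, as.integer(eta_map), as.numeric(omega2), sigma,
                eta_start, detail, 100L)
}

default_settings <- function(settings = list()) {
  out <- list(outer_iter = 400, polish = TRUE, polish_iter = 400,
              compute_se = TRUE, rel_tol = 1e-10)
  out[names(settings)] <- settings
  out
}

# crude naive-pooled starting values: clearance from the pooled mean
# steady-state concentration (AUC24 ~ 24 * Cbar), central volume from the
# pooled peak-trough swing, remaining parameters scaled from those
init_heuristic <- function(dataset) {
  obs <- dataset[dataset$EVID == 0 & dataset$MDV == 0, ]
  dose <- dataset[dataset$EVID == 1, ]
  cbar <- mean(obs$DV, na.rm = TRUE)
  per_id <- tapply(dose$AMT, dose$ID, function(a) mean(a[-1]) * 2) # daily maintenance
  daily <- mean(unlist(per_id), na.rm = TRUE)
  cl0 <- max(daily / (24 * cbar), 0.2)
  swing <- tapply(obs$DV, obs$ID, function(y) diff(range(y, na.rm = TRUE)))
  maint <- mean(tapply(dose$AMT, dose$ID, function(a) mean(a[-1])), na.rm = TRUE)
  v0 <- maint / max(mean(swing[swing > 0], na.rm = TRUE), 1e-6)
  if (!is.finite(v0)) v0 <- 10
  v0 <- min(max(v0, 2), 100)
  c(V = v0, V2 = 3 * v0, CL = cl0, Q = 2 * cl0)
}

#' Fit the population model by FOCE
#'
#' Maximises the FOCE-with-interaction marginal likelihood over the typical
#' values, IIV variances, residual SD and any covariate coefficients.
#' Variance-scale parameters are optimised on the log scale by a
#' quasi-Newton pass ([stats::nlminb()]) followed by a derivative-free
#' simplex polish; standard errors come from the central-difference Hessian
#' of the OFV at the optimum (`cov = 2 H^-1`), reported as SE, RSE% and a
#' normal-theory 95% CI. Empirical-Bayes etas and their shrinkage are
#' computed at the optimum.
#'
#' @param dataset a `pk_dataset`.
#' @param init starting values: a [population_model()], a named list with
#'   elements `theta`, `omega2`, `sigma`, or `NULL` for a naive-pooled
#'   heuristic start.
#' @param random_effects names of parameters carrying IIV (default CL, V2,
#'   Q, the final-model set).
#' @param cov_model optional list of [covariate_term()]s.
#' @param coefs_init starting covariate coefficients (default zeros).
#' @param settings list overriding `outer_iter`, `polish`, `polish_iter`,
#'   `compute_se`, `rel_tol`.
#' @return a `pop_fit` object: estimates, OFV, parameter table (Estimate,
#'   SE, RSE%, 95% CI, Shrinkage%), EBEs, shrinkage, convergence info.
#' @export
pop_fit <- function(dataset, init = NULL, random_effects = c("CL", "V2", "Q"),
                    cov_model = NULL, coefs_init = NULL,
                    settings = list()) {
  st <- default_settings(settings)
  dp <- prepare_nlme_data(dataset)
  n_par_data <- sum(lengths(dp$obs_y))
  if (n_par_data < 8) warning("fewer observations than parameters; fit is unidentifiable")
  cov_model <- resolve_refs(cov_model, dp$cov)
  k <- length(cov_model)
  if (is.null(coefs_init)) coefs_init <- numeric(k)

  if (is.null(init)) {
    theta0 <- init_heuristic(dataset)
    omega20 <- setNames(rep(0.2, length(random_effects)), random_effects)
    sigma0 <- 0.2
  } else {
    theta0 <- unlist(init$theta)[PARAM_NAMES]
    omega20 <- unlist(init$omega2)[random_effects]
    omega20[is.na(omega20)] <- 0.2
    names(omega20) <- random_effects
    sigma0 <- init$sigma
  }
  q <- length(random_effects)

  eta_env <- new.env()
  eta_env$eta <- matrix(0, dp$n, q)
  decode <- function(par) {
    list(theta = setNames(exp(par[1:4]), PARAM_NAMES),
         omega2 = setNames(exp(par[4 + seq_len(q)]), random_effects),
         sigma = unname(exp(par[5 + q])),
         coefs = if (k) par[5 + q + seq_len(k)] else numeric(0))
  }
  objective <- function(par) {
    p <- decode(par)
    res <- tryCatch(
      foce_eval(dp, p$theta, p$omega2, p$sigma, cov_model, p$coefs,
                eta_env$eta),
      error = function(e) NULL)
    if (is.null(res) || !is.finite(res$ofv)) return(1e10)
    eta_env$eta <- res$eta
    res$ofv
  }
  par0 <- c(log(theta0), log(omega20), log(sigma0), coefs_init)

  opt <- nlminb(par0, objective,
                control = list(iter.max = st$outer_iter, eval.max = 4 * st$outer_iter,
                               rel.tol = st$rel_tol))
  best <- list(par = opt$par, ofv = opt$objective, conv = opt$convergence == 0)
  if (st$polish) {
    # alternate simplex polish and quasi-Newton restarts until the OFV stops
    # moving; a cycle that gains < 0.01 OFV units confirms the optimum
    for (cycle in 1:5) {
      before <- best$ofv
      pol <- optim(best$par, objective, method = "Nelder-Mead",
                   control = list(maxit = st$polish_iter, reltol = 1e-10))
      if (pol$value < best$ofv) best <- list(par = pol$par, ofv = pol$value,
                                             conv = best$conv)
      re <- nlminb(best$par, objective,
                   control = list(iter.max = st$outer_iter, rel.tol = st$rel_tol))
      if (re$objective < best$ofv) best <- list(par = re$par, ofv = re$objective,
                                                conv = best$conv)
      if (before - best$ofv < 0.01) { best$conv <- TRUE; break }
    }
  }
  est <- decode(best$par)

  final <- foce_eval(dp, est$theta, est$omega2, est$sigma, cov_model, est$coefs,
                     eta_env$eta)
  eta <- final$eta
  colnames(eta) <- random_effects
  shr <- eta_shrinkage(eta, est$omega2)

  se_tab <- NULL
  if (st$compute_se) {
    se_tab <- tryCatch(
      fit_se_table(dp, est, cov_model, random_effects, eta_env$eta, shr),
      error = function(e) { warning("standard errors unavailable: ",
                                    conditionMessage(e)); NULL })
  }

  structure(list(theta = est$theta, omega2 = est$omega2, sigma = est$sigma,
                 coefs = est$coefs, cov_model = cov_model,
                 random_effects = random_effects,
                 ofv = best$ofv, converged = best$conv,
                 eta = eta, shrinkage = shr, parameter_table = se_tab,
                 n_subjects = dp$n, n_obs = n_par_data,
                 subject_conv = final$conv, dataset = dataset),
            class = "pop_fit")
}

natural_vec <- function(est, random_effects) {
  c(setNames(est$theta, paste0("tv", PARAM_NAMES)),
    setNames(est$omega2, paste0("omega2_", random_effects)),
    sigma = est$sigma,
    if (length(est$coefs)) setNames(est$coefs, paste0("beta", seq_along(est$coefs))))
}

fit_se_table <- function(dp, est, cov_model, random_effects, eta_warm, shr) {
  x0 <- natural_vec(est, random_effects)
  q <- length(random_effects); k <- length(est$coefs)
  fun <- function(x) {
    th <- setNames(x[1:4], PARAM_NAMES)
    w2 <- setNames(x[4 + seq_len(q)], random_effects)
    if (any(th <= 0) || any(w2 <= 0) || x[5 + q] <= 0) return(NA_real_)
    cf <- if (k) x[5 + q + seq_len(k)] else numeric(0)
    foce_eval(dp, th, w2, x[5 + q], cov_model, cf, eta_warm)$ofv
  }
  H <- central_hessian(fun, x0)
  cov <- tryCatch(2 * solve(H), error = function(e) stop("singular Hessian"))
  se <- sqrt(pmax(diag(cov), 0))
  shr_col <- rep(NA_real_, length(x0))
  shr_col[4 + seq_len(q)] <- shr[random_effects]
  data.frame(parameter = names(x0), estimate = unname(x0), se = se,
             rse_pct = 100 * se / abs(unname(x0)),
             ci_lo = unname(x0) - 1.96 * se, ci_hi = unname(x0) + 1.96 * se,
             shrinkage_pct = 100 * shr_col, row.names = NULL)
}

central_hessian <- function(fun, x0, rel_step = 1e-3) {
  n <- length(x0)
  h <- pmax(abs(x0), 1e-4) * rel_step
  H <- matrix(NA_real_, n, n)
  f0 <- fun(x0)
  for (i in seq_len(n)) {
    for (j in i:n) {
      if (i == j) {
        xp <- x0; xm <- x0
        xp[i] <- x0[i] + h[i]; xm[i] <- x0[i] - h[i]
        H[i, i] <- (fun(xp) - 2 * f0 + fun(xm)) / h[i]^2
      } else {
        xpp <- x0; xpm <- x0; xmp <- x0; xmm <- x0
        xpp[c(i, j)] <- x0[c(i, j)] + h[c(i, j)]
        xmm[c(i, j)] <- x0[c(i, j)] - h[c(i, j)]
        xpm[i] <- x0[i] + h[i]; xpm[j] <- x0[j] - h[j]
        xmp[i] <- x0[i] - h[i]; xmp[j] <- x0[j] + h[j]
        H[i, j] <- H[j, i] <- (fun(xpp) - fun(xpm) - fun(xmp) + fun(xmm)) /
          (4 * h[i] * h[j])
      }
    }
  }
  H
}

#' Eta shrinkage
#'
#' `1 - SD(EBE)/omega` per random effect: near 1 when the data carry no
#' subject-level information about that effect. Values above 0.5 flag a
#' random effect worth dropping (the rule that removed the effect on V in
#' the final model).
#'
#' @param eta matrix of empirical-Bayes etas (subjects x effects).
#' @param omega2 named IIV variances matching the eta columns.
#' @return named shrinkage fractions; `NA` where omega is 0.
#' @export
eta_shrinkage <- function(eta, omega2) {
  if (is.null(dim(eta))) eta <- matrix(eta, ncol = 1)
  if (nrow(eta) < 2) stop("need at least 2 subjects", call. = FALSE)
  out <- setNames(rep(NA_real_, length(omega2)), names(omega2))
  for (j in seq_along(omega2)) {
    if (omega2[j] > 0) out[j] <- 1 - sd(eta[, j]) / sqrt(omega2[j])
  }
  out
}

#' @export
print.pop_fit <- function(x, ...) {
  cat(sprintf("FOCE fit: %d subjects, %d observations, OFV = %.3f%s\n",
              x$n_subjects, x$n_obs, x$ofv,
              if (x$converged) "" else " (NOT converged)"))
  cat("  theta :", paste(sprintf("%s=%.4g", names(x$theta), x$theta), collapse = "  "), "\n")
  cat("  omega2:", paste(sprintf("%s=%.4g", names(x$omega2), x$omega2), collapse = "  "), "\n")
  cat("  sigma :", format(x$sigma, digits = 4), "\n")
  cat("  shrinkage:", paste(sprintf("%s=%.1f%%", names(x$shrinkage),
                                    100 * x$shrinkage), collapse = "  "), "\n")
  if (length(x$coefs))
    cat("  covariate coefs:", paste(sprintf("%.4g", x$coefs), collapse = "  "), "\n")
  invisible(x)
}

#' Stepwise covariate selection
#'
#' Forward addition then backward elimination on OFV changes: at each
#' forward step every remaining candidate is fitted and the best is added
#' if the OFV drops by more than `forward_dofv` (6.63, p = 0.01 on 1 df);
#' included terms are then removed one at a time and kept only if removal
#' raises the OFV by more than `backward_dofv` (10.83, p = 0.001). Ties in
#' the forward step (within 0.01) break to the fewest added parameters,
#' then alphabetically.
#'
#' @param dataset a `pk_dataset`.
#' @param base_fit the covariate-free [pop_fit()].
#' @param candidates list of [covariate_term()]s; default tests the twelve
#'   study covariates (AGE, TBW, BMI, IBW, ABW, SEX, SOFA, the three CrCL
#'   variants, SCR, GFR) on clearance.
#' @param forward_dofv,backward_dofv OFV thresholds.
#' @param settings fit settings for candidate fits (warm-started from the
#'   base fit; simplex polish off by default for speed).
#' @return a `covariate_steps` list: `final_terms`, `final_coefs`,
#'   `final_fit`, and a `log` data.frame of every tested step.
#' @export
stepwise_covariates <- function(dataset, base_fit, candidates = NULL,
                                forward_dofv = 6.63, backward_dofv = 10.83,
                                settings = list(polish = FALSE, compute_se = FALSE)) {
  if (is.null(candidates)) {
    covs <- c("AGE", "TBW", "BMI", "IBW", "ABW", "SEX", "SOFA",
              "CRCL_TBW", "CRCL_ABW", "CRCL_IBW", "SCR", "GFR")
    covs <- intersect(covs, names(dataset))
    candidates <- lapply(covs, function(cv) covariate_term("CL", cv))
  }
  label <- function(tm) paste0(tm$cov, "~", tm$param)
  init <- list(theta = base_fit$theta, omega2 = base_fit$omega2,
               sigma = base_fit$sigma)
  refit <- function(terms, coefs0) {
    pop_fit(dataset, init = init, random_effects = base_fit$random_effects,
            cov_model = terms, coefs_init = coefs0, settings = settings)
  }
  log_rows <- list()
  included <- list(); remaining <- candidates
  current_fit <- base_fit
  step <- 0L
  # ---- forward ----
  repeat {
    step <- step + 1L
    if (!length(remaining)) break
    trials <- lapply(remaining, function(tm) {
      f <- tryCatch(refit(c(included, list(tm)), c(current_fit$coefs, 0)),
                    error = function(e) NULL)
      if (is.null(f)) return(list(fit = NULL, dofv = -Inf))
      list(fit = f, dofv = current_fit$ofv - f$ofv)
    })
    dofv <- vapply(trials, function(x) x$dofv, 0)
    for (j in seq_along(remaining)) {
      log_rows[[length(log_rows) + 1L]] <-
        data.frame(phase = "forward", step = step,
                   term = label(remaining[[j]]), dofv = dofv[j],
                   decision = "tested")
    }
    ok <- which(dofv > forward_dofv)
    if (!length(ok)) break
    # tie-break: within 0.01 of the best, fewest parameters then alphabetical
    best_dofv <- max(dofv[ok])
    tied <- ok[dofv[ok] >= best_dofv - 0.01]
    labs <- vapply(remaining[tied], label, "")
    pick <- tied[order(labs)][1]
    log_rows[[length(log_rows) + 1L]] <-
      data.frame(phase = "forward", step = step,
                 term = label(remaining[[pick]]), dofv = dofv[pick],
                 decision = "added")
    included <- c(included, remaining[pick])
    current_fit <- trials[[pick]]$fit
    remaining <- remaining[-pick]
  }
  # ---- backward ----
  repeat {
    if (!length(included)) break
    worst <- NULL; worst_dofv <- Inf
    for (j in seq_along(included)) {
      f <- tryCatch(refit(included[-j], current_fit$coefs[-j]),
                    error = function(e) NULL)
      if (is.null(f)) next
      dofv_j <- f$ofv - current_fit$ofv # OFV increase on removal
      log_rows[[length(log_rows) + 1L]] <-
        data.frame(phase = "backward", step = step, term = label(included[[j]]),
                   dofv = dofv_j, decision = "tested")
      if (dofv_j < worst_dofv) { worst <- j; worst_dofv <- dofv_j; worst_fit <- f }
    }
    if (is.null(worst) || worst_dofv > backward_dofv) break
    log_rows[[length(log_rows) + 1L]] <-
      data.frame(phase = "backward", step = step, term = label(included[[worst]]),
                 dofv = worst_dofv, decision = "removed")
    included <- included[-worst]
    current_fit <- worst_fit
  }
  structure(list(final_terms = included,
                 final_coefs = current_fit$coefs,
                 final_fit = current_fit,
                 base_ofv = base_fit$ofv,
                 log = if (length(log_rows)) do.call(rbind, log_rows)
                       else data.frame(phase = character(0), step = integer(0),
                                       term = character(0), dofv = numeric(0),
                                       decision = character(0))),
            class = "covariate_steps")
}

#' Nonparametric bootstrap of the population fit
#'
#' Resamples subjects with replacement (same n), refits each replicate
#' warm-started from the point estimate, and summarises every parameter by
#' its replicate median, SE (SD across replicates), RSE% and 2.5-97.5
#' percentile CI. Replicates that fail to converge are dropped and counted;
#' more than 50% failures aborts.
#'
#' @param dataset a `pk_dataset`.
#' @param fit the final [pop_fit()].
#' @param n_resamples number of bootstrap replicates (1,000 in the source
#'   analysis; scale down for quick checks).
#' @param seed integer seed for the resampling.
#' @param settings fit settings per replicate (polish and SEs off by
#'   default).
#' @return a `pop_bootstrap` list: `summary` data.frame, `replicates`
#'   matrix, `n_failed`.
#' @export
pop_bootstrap <- function(dataset, fit, n_resamples = 200, seed = NULL,
                          settings = list(polish = FALSE, compute_se = FALSE)) {
  if (!is.null(seed)) set.seed(seed)
  ids <- unique(dataset$ID)
  n <- length(ids)
  init <- list(theta = fit$theta, omega2 = fit$omega2, sigma = fit$sigma)
  draws <- vector("list", n_resamples)
  n_failed <- 0L
  for (b in seq_len(n_resamples)) {
    take <- sample(ids, n, replace = TRUE)
    pieces <- lapply(seq_along(take), function(j) {
      d <- dataset[dataset$ID == take[j], ]
      d$ID <- j
      d
    })
    boot_dat <- do.call(rbind, pieces)
    class(boot_dat) <- class(dataset)
    f <- tryCatch(pop_fit(boot_dat, init = init,
                          random_effects = fit$random_effects,
                          cov_model = fit$cov_model,
                          coefs_init = fit$coefs, settings = settings),
                  error = function(e) NULL)
    if (is.null(f) || !is.finite(f$ofv)) { n_failed <- n_failed + 1L; next }
    draws[[b]] <- natural_vec(f, fit$random_effects)
  }
  if (n_failed > n_resamples / 2) {
    stop("more than half of bootstrap replicates failed (", n_failed, "/",
         n_resamples, ")", call. = FALSE)
  }
  rep_mat <- do.call(rbind, draws[!vapply(draws, is.null, TRUE)])
  qs <- apply(rep_mat, 2, quantile, probs = c(0.025, 0.5, 0.975), type = 5)
  summary <- data.frame(parameter = colnames(rep_mat),
                        median = qs[2, ], se = apply(rep_mat, 2, sd),
                        ci_lo = qs[1, ], ci_hi = qs[3, ], row.names = NULL)
  summary$rse_pct <- 100 * summary$se / abs(summary$median)
  structure(list(summary = summary, replicates = rep_mat,
                 n_resamples = n_resamples, n_failed = n_failed,
                 convergence_fraction = 1 - n_failed / n_resamples),
            class = "pop_bootstrap")
}
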