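#' Study design for synthetic cohorts
#'
#' Encodes the obese-cohort design this package emulates: 26 adults with
#' TBW 75-125 kg (median ~90) and BMI 30.04-40.35, dosed empirically with a
#' 100-200 mg loading infusion plus 50-100 mg q12h maintenance (1-h
#' infusions), and sampled at steady state on day 4 with either a rich
#' schedule (trough plus 1, 1.5, 2, 4, 6, 8 h post-dose) or a sparse
#' two-point schedule (trough and 2 h). The trough sample (C0h) is anchored
#' at t = 72 h, immediately before the morning maintenance dose.
#'
#' @param n_subjects cohort size (default 26).
#' @param fraction_rich fraction on the rich schedule (default 10/26).
#' @param rich_times,sparse_times post-dose sampling offsets (h) within one
#'   dosing interval.
#' @param sampling_day day of sampling; C0h falls at `(sampling_day - 1) * 24`.
#' @param loading_choices,maintenance_choices dose policies sampled uniformly
#'   per subject (mg).
#' @param infusion_duration bedside infusion duration (h).
#' @param tau dosing interval (h).
#' @param horizon dosing horizon (h).
#' @param lloq assay lower limit of quantitation for the summed B1+B2
#'   concentration (mg/L); observations below it are flagged and excluded
#'   from estimation input.
#' @param rich_n_sampler optional function returning a per-subject rich
#'   sample count in 4-7 (the study's rich schedules varied); `NULL` uses
#'   all seven nominal times.
#' @param covariates list of covariate-distribution settings; see Details.
#'
#' @details Covariate marginals honour the published medians and ranges:
#' TBW is a scaled Beta(2, 4) on 75-125 kg (median ~90.7), BMI uniform on
#' 30.04-40.35, height back-computed from TBW and BMI (redrawn if outside
#' 152.4-200 cm, the adult range consistent with the published IBW spread),
#' age discrete-uniform 18-83, serum creatinine lognormal
#' (median 76 umol/L) truncated to 34-368, SOFA near 10 on 5-17, GFR
#' lognormal (median 80.9) truncated to 11.26-149.57, and a 17:9
#' male:female ratio.
#'
#' @return an object of class `study_design` (a list).
#' @export
study_design <- function(n_subjects = 26, fraction_rich = 10 / 26,
                         rich_times = c(0, 1, 1.5, 2, 4, 6, 8),
                         sparse_times = c(0, 2),
                         sampling_day = 4,
                         loading_choices = c(100, 150, 200),
                         maintenance_choices = c(50, 75, 100),
                         infusion_duration = 1, tau = 12, horizon = 96,
                         lloq = 0.25, rich_n_sampler = NULL,
                         covariates = list()) {
  stopifnot(fraction_rich >= 0, fraction_rich <= 1,
            all(rich_times >= 0), all(rich_times < tau))
  cov_def <- list(p_male = 17 / 26,
                  tbw_range = c(75, 125), tbw_beta = c(2, 4),
                  bmi_range = c(30.04, 40.35),
                  height_range = c(152.4, 200),
                  age_range = c(18, 83),
                  scr_meanlog = log(76), scr_sdlog = 0.55,
                  scr_range = c(34, 368),
                  sofa_range = c(5, 17), sofa_mean = 10, sofa_sd = 3,
                  gfr_meanlog = log(80.9), gfr_sdlog = 0.5,
                  gfr_range = c(11.26, 149.57))
  cov_def[names(covariates)] <- covariates
  structure(list(n_subjects = n_subjects, fraction_rich = fraction_rich,
                 rich_times = rich_times, sparse_times = sparse_times,
                 sampling_day = sampling_day,
                 loading_choices = loading_choices,
                 maintenance_choices = maintenance_choices,
                 infusion_duration = infusion_duration, tau = tau,
                 horizon = horizon, lloq = lloq,
                 rich_n_sampler = rich_n_sampler, covariates = cov_def),
            class = "study_design")
}

draw_truncated <- function(n, rfun, range, max_tries = 1000) {
  out <- rfun(n)
  for (i in seq_len(max_tries)) {
    bad <- out < range[1] | out > range[2]
    if (!any(bad)) return(out)
    out[bad] <- rfun(sum(bad))
  }
  pmin(pmax(out, range[1]), range[2])
}

draw_covariates <- function(n, cv, max_tries = 100) {
  sex <- rbinom(n, 1, 1 - cv$p_male) # 0 = male, 1 = female
  tbw <- cv$tbw_range[1] + diff(cv$tbw_range) * rbeta(n, cv$tbw_beta[1], cv$tbw_beta[2])
  bmi <- runif(n, cv$bmi_range[1], cv$bmi_range[2])
  ht <- sqrt(tbw / bmi) * 100
  for (i in seq_len(max_tries)) { # infeasible TBW/BMI pairs: re-draw
    bad <- ht < cv$height_range[1] | ht > cv$height_range[2]
    if (!any(bad)) break
    tbw[bad] <- cv$tbw_range[1] + diff(cv$tbw_range) * rbeta(sum(bad), cv$tbw_beta[1], cv$tbw_beta[2])
    bmi[bad] <- runif(sum(bad), cv$bmi_range[1], cv$bmi_range[2])
    ht[bad] <- sqrt(tbw[bad] / bmi[bad]) * 100
    if (i == max_tries) stop("could not draw feasible TBW/BMI/height", call. = FALSE)
  }
  age <- sample(seq(cv$age_range[1], cv$age_range[2]), n, replace = TRUE)
  scr <- draw_truncated(n, function(k) rlnorm(k, cv$scr_meanlog, cv$scr_sdlog), cv$scr_range)
  sofa <- round(draw_truncated(n, function(k) rnorm(k, cv$sofa_mean, cv$sofa_sd), cv$sofa_range))
  gfr <- draw_truncated(n, function(k) rlnorm(k, cv$gfr_meanlog, cv$gfr_sdlog), cv$gfr_range)
  derive_body_metrics(data.frame(ID = seq_len(n), SEX = sex, AGE = age, HT = ht,
                                 TBW = tbw, SCR = scr, SOFA = sofa, GFR = gfr))
}

#' Generate a synthetic study cohort
#'
#' Draws covariates, a dose policy, individual PK parameters and noisy day-4
#' observations for each subject, and flags observations below the LLOQ.
#' Output is a NONMEM-style long dataset (see [write_pk_dataset()] for the
#' column contract).
#'
#' @param design a [study_design()].
#' @param model a [population_model()].
#' @param seed optional integer seed; fixed seeds give bit-identical cohorts.
#' @return a `pk_dataset`: data.frame with dose rows (EVID 1) and
#'   observation rows (EVID 0) carrying covariate columns, plus attributes
#'   `n_blq` (flagged observation count) and `n_truncated`.
#' @export
generate_cohort <- function(design, model, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- design$n_subjects
  cov <- draw_covariates(n, design$covariates)
  pars <- sample_individuals(model, n)
  n_rich <- round(design$fraction_rich * n)
  is_rich <- seq_len(n) %in% sample(seq_len(n), n_rich)
  t_anchor <- (design$sampling_day - 1) * 24
  n_trunc <- 0L
  rows <- vector("list", n)
  pick <- function(x) if (length(x) == 1) x else sample(x, 1)
  for (i in seq_len(n)) {
    loading <- pick(design$loading_choices)
    maint <- pick(design$maintenance_choices)
    reg <- dosing_regimen(loading, maint, tau = design$tau,
                          horizon = design$horizon,
                          infusion_duration = design$infusion_duration)
    offs <- if (is_rich[i]) {
      if (is.null(design$rich_n_sampler)) design$rich_times
      else { # always keep the trough; subsample the rest
        k <- design$rich_n_sampler()
        sort(c(0, sample(setdiff(design$rich_times, 0), k - 1)))
      }
    } else design$sparse_times
    times <- t_anchor + offs
    dv <- simulate_observations(pars[i, ], reg, times, sigma = model$sigma,
                                error_model = model$error_model)
    n_trunc <- n_trunc + attr(dv, "n_truncated")
    dose_rows <- data.frame(ID = i, TIME = reg$start, AMT = reg$amount,
                            RATE = reg$rate, EVID = 1L, DV = NA_real_,
                            MDV = 1L, BLQ = 0L)
    obs_rows <- data.frame(ID = i, TIME = times, AMT = NA_real_,
                           RATE = NA_real_, EVID = 0L, DV = as.numeric(dv),
                           MDV = 0L, BLQ = 0L)
    rows[[i]] <- rbind(dose_rows, obs_rows)
  }
  dat <- do.call(rbind, rows)
  dat <- dat[order(dat$ID, dat$TIME, -dat$EVID), ]
  dat <- merge(dat, cov, by = "ID", sort = FALSE)
  dat <- dat[order(dat$ID, dat$TIME, -dat$EVID), ]
  rownames(dat) <- NULL
  class(dat) <- c("pk_dataset", "data.frame")
  dat <- censor_lloq(dat, design$lloq)
  attr(dat, "n_truncated") <- n_trunc
  dat
}

#' Flag and exclude observations below the LLOQ
#'
#' Observation rows with a concentration strictly below `lloq` get
#' `BLQ = 1`, `MDV = 1` and their DV removed, mirroring the study's
#' exclusion of below-quantitation samples from the analysis dataset.
#'
#' @param dataset a `pk_dataset` (long format).
#' @param lloq lower limit of quantitation (mg/L), >= 0.
#' @return the dataset with BLQ flags applied and attribute `n_blq`.
#' @export
censor_lloq <- function(dataset, lloq) {
  if (lloq < 0) stop("lloq must be >= 0", call. = FALSE)
  blq <- dataset$EVID == 0 & !is.na(dataset$DV) & dataset$DV < lloq
  dataset$BLQ[blq] <- 1L
  dataset$MDV[blq] <- 1L
  dataset$DV[blq] <- NA_real_
  attr(dataset, "n_blq") <- sum(dataset$BLQ == 1 & dataset$EVID == 0)
  dataset
}
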