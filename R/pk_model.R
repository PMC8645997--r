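#' Two-compartment PK parameter set
#'
#' Structural parameters for one subject (or the typical individual):
#' central volume V (L), peripheral volume V2 (L), clearance CL (L/h) and
#' inter-compartmental clearance Q (L/h). All must be strictly positive;
#' the implied micro-constants k10 = CL/V, k12 = Q/V, k21 = Q/V2 and hybrid
#' rate constants alpha > beta > 0 then follow.
#'
#' @param V,V2,CL,Q structural parameters, all > 0.
#' @return an object of class `pk_params`.
#' @export
pk_params <- function(V, V2, CL, Q) {
  vals <- c(V = V, V2 = V2, CL = CL, Q = Q)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all PK parameters must be finite and > 0", call. = FALSE)
  }
  structure(as.list(vals), class = "pk_params")
}

#' Build an infusion schedule
#'
#' A dosing regimen is an ordered table of infusion events (start time,
#' amount, rate); superposition handles any overlap. The standard pattern is
#' a loading infusion at t = 0 followed by maintenance infusions every `tau`
#' hours from t = `tau` up to (not including) the horizon. Exactly one of
#' `infusion_rate` (mg/h, fixed-rate convention used in dosing simulations)
#' or `infusion_duration` (h, fixed-duration convention used at the bedside)
#' must be given.
#'
#' @param loading loading dose (mg) given at t = 0; `NULL` for none.
#' @param maintenance maintenance dose (mg) repeated every `tau` h; `NULL`
#'   for none.
#' @param tau dosing interval (h), default 12.
#' @param horizon schedule horizon (h), default 96 (through day 4).
#' @param infusion_rate infusion rate in mg/h applied to every event.
#' @param infusion_duration infusion duration in h applied to every event.
#' @param first_maintenance time of the first maintenance dose (h), default
#'   `tau`.
#' @return a `dosing_regimen`: data.frame with columns `start`, `amount`,
#'   `rate`, plus attributes `tau` and `horizon`.
#' @examples
#' dosing_regimen(loading = 200, maintenance = 100, infusion_rate = 50)
#' @export
dosing_regimen <- function(loading = NULL, maintenance = NULL, tau = 12,
                           horizon = 96, infusion_rate = NULL,
                           infusion_duration = NULL, first_maintenance = tau) {
  if (is.null(infusion_rate) == is.null(infusion_duration)) {
    stop("give exactly one of infusion_rate or infusion_duration", call. = FALSE)
  }
  if (tau <= 0) stop("tau must be > 0", call. = FALSE)
  start <- numeric(0); amount <- numeric(0)
  if (!is.null(loading) && loading > 0) { start <- 0; amount <- loading }
  if (!is.null(maintenance) && maintenance > 0) {
    mt <- seq(first_maintenance, horizon - 1e-9, by = tau)
    start <- c(start, mt); amount <- c(amount, rep(maintenance, length(mt)))
  }
  rate <- if (is.null(infusion_rate)) amount / infusion_duration
          else rep(infusion_rate, length(amount))
  regimen_from_events(data.frame(start = start, amount = amount, rate = rate),
                      tau = tau, horizon = horizon)
}

#' @rdname dosing_regimen
#' @param events data.frame with columns `start` (h), `amount` (mg > 0),
#'   `rate` (mg/h > 0) for arbitrary schedules.
#' @export
regimen_from_events <- function(events, tau = 12, horizon = 96) {
  stopifnot(all(c("start", "amount", "rate") %in% names(events)))
  if (nrow(events) && (any(events$amount <= 0) || any(events$rate <= 0))) {
    stop("dose amounts and rates must be > 0", call. = FALSE)
  }
  events <- events[order(events$start), , drop = FALSE]
  rownames(events) <- NULL
  structure(events, tau = tau, horizon = horizon,
            class = c("dosing_regimen", "data.frame"))
}

as_params_vec <- function(params) {
  if (inherits(params, "pk_params")) unlist(params)
  else {
    p <- unlist(params)[c("V", "V2", "CL", "Q")]
    if (any(is.na(p))) stop("params must carry V, V2, CL, Q", call. = FALSE)
    p
  }
}

#' Central-compartment concentration
#'
#' Closed-form concentration (mg/L) at arbitrary times under an arbitrary
#' infusion schedule, by superposition of the biexponential infusion /
#' post-infusion solution of the two-compartment model. Continuous in time
#' and non-negative; an empty regimen gives 0 everywhere.
#'
#' @param params a [pk_params()] (or named list/vector with V, V2, CL, Q).
#' @param regimen a [dosing_regimen()].
#' @param times times (h) at which to evaluate, all >= 0.
#' @return concentrations (mg/L), same length as `times`.
#' @export
pk_conc <- function(params, regimen, times) {
  if (any(times < 0)) stop("times must be >= 0", call. = FALSE)
  p <- as_params_vec(params)
  if (nrow(regimen) == 0) return(numeric(length(times)) * 0)
  .pk2_conc_cpp(as.numeric(times), p[["V"]], p[["V2"]], p[["CL"]], p[["Q"]],
                regimen$start, regimen$amount, regimen$rate)
}

#' Exact AUC of the central concentration
#'
#' Analytic integral of the superposed closed-form solution over
#' `[t0, t1]` (mg.h/L) -- the antiderivative of each exponential term, so
#' additive over windows and free of quadrature error.
#'
#' @inheritParams pk_conc
#' @param t0,t1 window bounds (h), `0 <= t0 < t1`.
#' @return AUC in mg.h/L.
#' @export
pk_auc <- function(params, regimen, t0, t1) {
  if (!(t0 >= 0 && t1 > t0)) stop("need 0 <= t0 < t1", call. = FALSE)
  p <- as_params_vec(params)
  if (nrow(regimen) == 0) return(0)
  .pk2_auc_cpp(p[["V"]], p[["V2"]], p[["CL"]], p[["Q"]],
               regimen$start, regimen$amount, regimen$rate, t0, t1)
}

#' Exposure windows for q12h regimens
#'
#' The day-4 24-h exposure window used for the steady-state AUC metric
#' (`[72, 96)` h with the loading dose at t = 0) and the first-24-h window
#' used for the AUC/MIC PK/PD index (`[0, 24)` h). Both are 24 h long.
#'
#' @param which `"day4"` (AUC_ss,24h) or `"first24"` (AUC_0-24).
#' @return numeric `c(t0, t1)`.
#' @export
steady_state_window <- function(which = c("day4", "first24")) {
  switch(match.arg(which), day4 = c(72, 96), first24 = c(0, 24))
}
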