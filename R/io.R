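# Dataset and configuration I/O: the NONMEM-style rectangular CSV that the
# estimation pipeline consumes, and YAML run configuration for the model
# block. Output files carry a provenance comment header (version, seed,
# config hash) so seeded stages reproduce bit-for-bit.

DATASET_COLS <- c("ID", "TIME", "AMT", "RATE", "EVID", "DV", "MDV", "BLQ")

#' Write a study dataset CSV
#'
#' NONMEM-style long format: dose rows (`EVID = 1`) carry AMT (mg) and RATE
#' (mg/h) with empty DV; observation rows (`EVID = 0`) carry DV (mg/L)
#' unless flagged BLQ. Covariate columns are carried through unchanged.
#' Lines starting with `#` hold provenance (package version, seed, config
#' hash) and are skipped on read.
#'
#' @param dataset a `pk_dataset`.
#' @param path output file path.
#' @param seed,config_hash optional provenance fields recorded in the header.
#' @return `path`, invisibly.
#' @export
write_pk_dataset <- function(dataset, path, seed = NULL, config_hash = NULL) {
  validate_pk_dataset(dataset)
  hdr <- c(sprintf("# polyBpopPK %s",
                   as.character(utils::packageVersion("polyBpopPK"))),
           if (!is.null(seed)) sprintf("# seed: %s", seed),
           if (!is.null(config_hash)) sprintf("# config: %s", config_hash))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  write.csv(as.data.frame(dataset), con, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a study dataset CSV
#'
#' Validates the schema on load: mandatory columns present, dose rows have
#' positive AMT and no DV, observation rows have DV unless BLQ-flagged, and
#' TIME is non-decreasing within subject. BLQ rows are retained with their
#' flag; exclusion from estimation happens downstream.
#'
#' @param path CSV path written by [write_pk_dataset()] (or compatible).
#' @return a `pk_dataset` data.frame.
#' @export
read_pk_dataset <- function(path) {
  dat <- read.csv(path, comment.char = "#")
  validate_pk_dataset(dat)
  class(dat) <- c("pk_dataset", "data.frame")
  dat
}

validate_pk_dataset <- function(dat) {
  miss <- setdiff(DATASET_COLS, names(dat))
  if (length(miss)) {
    stop("dataset is missing mandatory column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  if (any(dat$TIME < 0, na.rm = TRUE)) stop("negative TIME", call. = FALSE)
  bad_t <- unlist(tapply(dat$TIME, dat$ID, function(t) any(diff(t) < 0)))
  if (any(bad_t)) {
    stop("TIME not non-decreasing within subject(s): ",
         paste(names(bad_t)[bad_t], collapse = ", "), call. = FALSE)
  }
  dose <- dat$EVID == 1
  if (any(dose & (is.na(dat$AMT) | dat$AMT <= 0))) {
    stop("dose rows must have AMT > 0", call. = FALSE)
  }
  obs <- dat$EVID == 0
  bad_dv <- obs & is.na(dat$DV) & dat$BLQ == 0 & dat$MDV == 0
  if (any(bad_dv)) {
    stop("observation row(s) missing DV without BLQ/MDV flag: row ",
         paste(which(bad_dv), collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}

#' Read / write the model configuration
#'
#' YAML round-trip of a [population_model()]: keys `theta.{V,V2,CL,Q}`,
#' `omega2.{...}`, `sigma`, `error_model`. Unknown top-level keys are
#' rejected with an explicit error.
#'
#' @param path YAML file path.
#' @return for `read_model_config`, a [population_model()].
#' @export
read_model_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  known <- c("theta", "omega2", "sigma", "error_model")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  population_model(theta = unlist(cfg$theta), omega2 = unlist(cfg$omega2),
                   sigma = cfg$sigma,
                   error_model = cfg$error_model %||% "proportional")
}

#' @rdname read_model_config
#' @param model a [population_model()].
#' @export
write_model_config <- function(model, path) {
  yaml::write_yaml(list(theta = as.list(model$theta),
                        omega2 = as.list(model$omega2),
                        sigma = model$sigma,
                        error_model = model$error_model), path)
  invisible(path)
}

#' Write the fit report
#'
#' Parameter table (Estimate, SE, RSE%, 95% CI, Shrinkage%) as CSV plus a
#' small human-readable text summary next to it.
#'
#' @param fit a [pop_fit()].
#' @param path_prefix output prefix; writes `<prefix>.csv` and
#'   `<prefix>.txt`.
#' @return the CSV path, invisibly.
#' @export
write_fit_report <- function(fit, path_prefix) {
  csv <- paste0(path_prefix, ".csv")
  tab <- fit$parameter_table
  if (is.null(tab)) {
    tab <- data.frame(parameter = names(natural_vec(fit, fit$random_effects)),
                      estimate = unname(natural_vec(fit, fit$random_effects)))
  }
  write.csv(tab, csv, row.names = FALSE)
  txt <- paste0(path_prefix, ".txt")
  con <- file(txt, "w")
  on.exit(close(con))
  writeLines(utils::capture.output(print(fit)), con)
  invisible(csv)
}
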