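#' Ideal body weight (Devine)
#'
#' IBW in kg from sex and height: `[height(cm)/2.54 - 60] * 2.3 + 50` for
#' males and the same with 45.5 kg intercept for females. Heights below
#' 152.4 cm (60 in) give a negative bracket term; the formula value is
#' returned unchanged with a warning, since the obese cohorts this package
#' targets (TBW >= 75 kg, BMI >= 30) never reach that region.
#'
#' @param sex `"male"` or `"female"` (vectorised; also accepts 0 = male,
#'   1 = female as used in the dataset CSV).
#' @param height_cm height in cm, > 0.
#' @return ideal body weight in kg.
#' @examples
#' ideal_body_weight("male", 177.8) # 73.0
#' @export
ideal_body_weight <- function(sex, height_cm) {
  if (any(!is.finite(height_cm)) || any(height_cm <= 0)) {
    stop("height must be positive and finite", call. = FALSE)
  }
  sex <- recode_sex(sex)
  if (any(height_cm < 152.4)) {
    warning("height below 152.4 cm: IBW bracket term is negative; ",
            "returning the formula value unclamped")
  }
  (height_cm / 2.54 - 60) * 2.3 + ifelse(sex == "male", 50, 45.5)
}

#' Adjusted body weight
#'
#' `ABW = IBW + 0.4 * (TBW - IBW)`, the affine interpolation
#' `0.6 * IBW + 0.4 * TBW` used to scale doses and creatinine clearance in
#' obese patients.
#'
#' @param ibw ideal body weight (kg), > 0.
#' @param tbw total body weight (kg), > 0.
#' @return adjusted body weight in kg.
#' @export
adjusted_body_weight <- function(ibw, tbw) {
  if (any(ibw <= 0) || any(tbw <= 0)) stop("weights must be positive", call. = FALSE)
  ibw + 0.4 * (tbw - ibw)
}

#' Cockcroft-Gault creatinine clearance
#'
#' `(140 - age) * weight / (72 * SCr[mg/dL])`, times 0.85 for females.
#' Serum creatinine is taken in umol/L and converted by the standard factor
#' 88.4 umol/L per mg/dL. The weight argument selects the variant: passing
#' TBW, ABW or IBW yields CrCL, adjusted CrCL or ideal CrCL respectively.
#'
#' @param sex `"male"`/`"female"` (or 0/1).
#' @param age years, in `[18, 130)`.
#' @param weight_kg body weight used in the numerator (kg).
#' @param scr_umol_L serum creatinine in umol/L, > 0.
#' @return creatinine clearance in mL/min.
#' @export
cockcroft_gault <- function(sex, age, weight_kg, scr_umol_L) {
  if (any(scr_umol_L <= 0)) stop("serum creatinine must be positive", call. = FALSE)
  if (any(age <= 0) || any(age >= 130)) stop("age out of range", call. = FALSE)
  if (any(weight_kg <= 0)) stop("weight must be positive", call. = FALSE)
  sex <- recode_sex(sex)
  scr_mg_dl <- scr_umol_L / 88.4
  (140 - age) * weight_kg / (72 * scr_mg_dl) * ifelse(sex == "female", 0.85, 1)
}

recode_sex <- function(sex) {
  if (is.numeric(sex)) sex <- ifelse(sex == 0, "male", "female")
  sex <- tolower(as.character(sex))
  if (!all(sex %in% c("male", "female"))) {
    stop("sex must be 'male'/'female' or 0/1", call. = FALSE)
  }
  sex
}

#' Append derived body-size and renal covariates
#'
#' Adds BMI, IBW, ABW and the three Cockcroft-Gault creatinine-clearance
#' variants (by TBW, ABW and IBW) to a covariate table holding SEX
#' (0 = male, 1 = female), AGE (y), HT (cm), TBW (kg) and SCR (umol/L).
#'
#' @param covariates data.frame with columns SEX, AGE, HT, TBW, SCR.
#' @return the input with columns BMI, IBW, ABW, CRCL_TBW, CRCL_ABW,
#'   CRCL_IBW appended.
#' @export
derive_body_metrics <- function(covariates) {
  need <- c("SEX", "AGE", "HT", "TBW", "SCR")
  miss <- setdiff(need, names(covariates))
  if (length(miss)) stop("missing covariate columns: ", paste(miss, collapse = ", "),
                         call. = FALSE)
  covariates$BMI <- covariates$TBW / (covariates$HT / 100)^2
  covariates$IBW <- ideal_body_weight(covariates$SEX, covariates$HT)
  covariates$ABW <- adjusted_body_weight(covariates$IBW, covariates$TBW)
  covariates$CRCL_TBW <- cockcroft_gault(covariates$SEX, covariates$AGE,
                                         covariates$TBW, covariates$SCR)
  covariates$CRCL_ABW <- cockcroft_gault(covariates$SEX, covariates$AGE,
                                         covariates$ABW, covariates$SCR)
  covariates$CRCL_IBW <- cockcroft_gault(covariates$SEX, covariates$AGE,
                                         covariates$IBW, covariates$SCR)
  covariates
}
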