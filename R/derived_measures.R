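#' Cockcroft-Gault creatinine clearance
#'
#' Estimates creatinine clearance (mL/min) as
#' \deqn{ClCr = \frac{(140 - age) \times weight}{72 \times S_{cr}}}
#' multiplied by 0.85 in women. Serum creatinine is in mg/dL, age in years,
#' weight in kg. The 72 groups with serum creatinine in the denominator
#' (the standard form of the formula).
#'
#' @param scr serum creatinine, mg/dL, > 0.
#' @param age years, in [18, 140).
#' @param weight kg, > 0.
#' @param sex \code{"female"} or \code{"male"}.
#' @return creatinine clearance in mL/min.
#' @examples
#' cockcroft_gault(1.0, 40, 72, "male")    # 100
#' cockcroft_gault(1.0, 40, 72, "female")  # 85
#' @export
cockcroft_gault <- function(scr, age, weight, sex) {
  if (!is.numeric(scr) || is.na(scr) || scr <= 0)
    stop("scr must be a positive serum creatinine in mg/dL", call. = FALSE)
  if (!is.numeric(age) || is.na(age) || age < 18 || age >= 140)
    stop("age must be in [18, 140) years", call. = FALSE)
  if (!is.numeric(weight) || is.na(weight) || weight <= 0)
    stop("weight must be positive (kg)", call. = FALSE)
  sex <- match.arg(sex, c("female", "male"))
  out <- (140 - age) * weight / (72 * scr)
  if (sex == "female") out <- out * 0.85
  out
}

#' Simplified MDRD glomerular filtration rate
#'
#' Estimates GFR (mL/min/1.73m2) by the simplified (four-variable) MDRD
#' formula:
#' \deqn{GFR = 186 \times S_{cr}^{-1.154} \times age^{-0.203}
#'       \times 0.742^{[female]} \times 1.21^{[black]}}
#' with serum creatinine in mg/dL (the 186 constant belongs to the mg/dL
#' convention).
#'
#' @param scr serum creatinine, mg/dL, > 0.
#' @param age years; >= 18 unless \code{check_range = FALSE}.
#' @param sex \code{"female"} or \code{"male"}.
#' @param black_ethnicity logical.
#' @param check_range disable the adult age-range check (diagnostics mode,
#'   for analytic evaluation of the closed form at arbitrary ages).
#' @return estimated GFR in mL/min/1.73m2.
#' @examples
#' smdrd_gfr(1.0, 50, "male")  # 186 * 50^-0.203 ~ 84.3
#' @export
smdrd_gfr <- function(scr, age, sex, black_ethnicity = FALSE,
                      check_range = TRUE) {
  if (!is.numeric(scr) || is.na(scr) || scr <= 0)
    stop("scr must be a positive serum creatinine in mg/dL", call. = FALSE)
  if (!is.numeric(age) || is.na(age) || age <= 0)
    stop("age must be positive", call. = FALSE)
  if (check_range && age < 18)
    stop("age must be >= 18 years (set check_range = FALSE for analytic use)",
         call. = FALSE)
  sex <- match.arg(sex, c("female", "male"))
  out <- 186 * scr^(-1.154) * age^(-0.203)
  if (sex == "female") out <- out * 0.742
  if (isTRUE(black_ethnicity)) out <- out * 1.21
  out
}

#' Body-mass index
#'
#' @param weight kg, > 0.
#' @param height m, > 0.
#' @return BMI in kg/m2 (weight / height^2).
#' @examples
#' bmi(80, 2.0)  # 20
#' @export
bmi <- function(weight, height) {
  if (!is.numeric(weight) || is.na(weight) || weight <= 0)
    stop("weight must be positive (kg)", call. = FALSE)
  if (!is.numeric(height) || is.na(height) || height <= 0)
    stop("height must be positive (m)", call. = FALSE)
  weight / height^2
}

#' Convert serum creatinine from umol/L to mg/dL
#'
#' @param x creatinine in umol/L.
#' @return creatinine in mg/dL (x / 88.4).
#' @export
umol_to_mgdl <- function(x) x / 88.4

#' Derived renal quantities and reference-range flags
#'
#' Computes the Cockcroft-Gault clearance and simplified-MDRD GFR from the
#' renal panel and demographics, and flags each available measurement
#' against its (sex-specific where applicable) closed reference interval.
#' Boundary values count as within range; missing measurements flag
#' \code{"unknown"}. The clearance flag uses the measured clearance when one
#' is available, otherwise the Cockcroft-Gault estimate. LV diameters are
#' flagged against their mean +/- tolerance reference bands.
#'
#' @param renal an \code{\link{renal_panel}}.
#' @param demographics an \code{\link{demographics}} object.
#' @param cardiac an \code{\link{cardiac_panel}} (for the diameter flags);
#'   may be omitted.
#' @param config an \code{\link{hlm_config}}.
#' @return a list of class \code{hlm_derived} with elements
#'   \code{clcr_cg}, \code{gfr_smdrd}, \code{clcr_used},
#'   \code{clcr_source} (\code{"measured"}/\code{"cockcroft_gault"}/
#'   \code{"none"}), range flags \code{clcr_flag}, \code{scr_flag},
#'   \code{bun_flag}, \code{cystatin_flag}, \code{lvdd_flag},
#'   \code{lvsd_flag}, and \code{bmi}.
#' @export
flag_reference_ranges <- function(renal, demographics,
                                  cardiac = cardiac_panel(),
                                  config = hlm_config()) {
  d <- demographics
  scr <- renal$serum_creatinine
  clcr_cg <- if (!is.na(scr) && scr > 0)
    cockcroft_gault(scr, d$age, d$weight, d$sex) else NA_real_
  gfr <- if (!is.na(scr) && scr > 0)
    smdrd_gfr(scr, d$age, d$sex, d$black_ethnicity) else NA_real_

  if (!is.na(renal$measured_clcr)) {
    clcr_used <- renal$measured_clcr; clcr_source <- "measured"
  } else if (!is.na(clcr_cg)) {
    clcr_used <- clcr_cg; clcr_source <- "cockcroft_gault"
  } else {
    clcr_used <- NA_real_; clcr_source <- "none"
  }
  clcr_ref <- if (d$sex == "female") config$clcr_normal_female
              else config$clcr_normal_male

  structure(list(
    clcr_cg = clcr_cg,
    gfr_smdrd = gfr,
    clcr_used = clcr_used,
    clcr_source = clcr_source,
    clcr_flag = range_flag(clcr_used, clcr_ref),
    scr_flag = range_flag(scr, config$scr_normal),
    bun_flag = range_flag(renal$bun, c(0, config$bun_upper)),
    cystatin_flag = range_flag(renal$cystatin_c, c(0, config$cystatin_upper)),
    lvdd_flag = range_flag(cardiac$lv_end_diastolic_diameter,
                           diam_interval(config$lvdd_normal)),
    lvsd_flag = range_flag(cardiac$lv_end_systolic_diameter,
                           diam_interval(config$lvsd_normal)),
    bmi = if (!is.na(d$weight) && !is.na(d$height) && d$weight > 0 && d$height > 0)
      bmi(d$weight, d$height) else NA_real_
  ), class = "hlm_derived")
}
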