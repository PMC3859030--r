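#' Construct an HLM patient record
#'
#' A patient record bundles demographics with five clinical panels. Every
#' clinical flag is a tristate (\code{"present"}/\code{"absent"}/
#' \code{"unknown"}); every measurement is numeric or \code{NA}. Unknown is
#' never silently coerced to absent: the stage engines treat unknown
#' conservatively and report data completeness.
#'
#' Units are fixed: age in years, weight in kg, height in m, pressures in
#' mmHg, serum creatinine in mg/dL, cystatin C in mg/L, LV diameters in mm.
#' A creatinine value supplied in umol/L must be converted at the I/O layer
#' (\code{\link{umol_to_mgdl}}).
#'
#' @param patient_id opaque identifier, unique within a cohort.
#' @param demographics,cardiac,hemodynamics,pulmonary,renal,hepatic,neuro
#'   panel objects from the matching constructors.
#' @return an object of class \code{hlm_record}.
#' @seealso \code{\link{validate_record}}, \code{\link{classify}}
#' @export
hlm_record <- function(patient_id,
                       demographics,
                       cardiac = cardiac_panel(),
                       hemodynamics = hemodynamic_panel(),
                       pulmonary = pulmonary_signs(),
                       renal = renal_panel(),
                       hepatic = hepatic_panel(),
                       neuro = neuro_panel()) {
  stopifnot(is.character(patient_id), length(patient_id) == 1L, nzchar(patient_id))
  structure(list(
    patient_id   = patient_id,
    demographics = demographics,
    cardiac      = cardiac,
    hemodynamics = hemodynamics,
    pulmonary    = pulmonary,
    renal        = renal,
    hepatic      = hepatic,
    neuro        = neuro
  ), class = "hlm_record")
}

#' @param age years, integer-valued, >= 18.
#' @param sex \code{"female"} or \code{"male"}.
#' @param black_ethnicity logical; used by the simplified-MDRD formula.
#' @param weight kg, > 0.
#' @param height m, > 0.
#' @rdname hlm_record
#' @export
demographics <- function(age, sex, weight, height, black_ethnicity = FALSE) {
  structure(list(age = as.numeric(age), sex = as.character(sex),
                 black_ethnicity = isTRUE(black_ethnicity),
                 weight = as.numeric(weight), height = as.numeric(height)),
            class = "hlm_demographics")
}

num_or_na <- function(x) if (is.null(x) || length(x) == 0L) NA_real_ else as.numeric(x)

#' @param ejection_fraction \% of LV end-diastolic volume, or NA.
#' @param systolic_dysfunction,diastolic_dysfunction,lv_hypertrophy,lv_remodeling,rv_dysfunction
#'   tristate flags (any encoding accepted by \code{\link{as_tristate}}).
#' @param previous_mi one of \code{"none"}, \code{"nstemi"}, \code{"stemi"},
#'   \code{"unknown"}.
#' @param lv_end_diastolic_diameter,lv_end_systolic_diameter mm, or NA.
#' @rdname hlm_record
#' @export
cardiac_panel <- function(ejection_fraction = NA,
                          systolic_dysfunction = "unknown",
                          diastolic_dysfunction = "unknown",
                          lv_hypertrophy = "unknown",
                          previous_mi = "unknown",
                          lv_end_diastolic_diameter = NA,
                          lv_end_systolic_diameter = NA,
                          lv_remodeling = "unknown",
                          rv_dysfunction = "unknown") {
  previous_mi <- tolower(trimws(as.character(previous_mi)))
  if (is.na(previous_mi) || previous_mi == "") previous_mi <- "unknown"
  structure(list(
    ejection_fraction = num_or_na(ejection_fraction),
    systolic_dysfunction = as_tristate(systolic_dysfunction),
    diastolic_dysfunction = as_tristate(diastolic_dysfunction),
    lv_hypertrophy = as_tristate(lv_hypertrophy),
    previous_mi = previous_mi,
    lv_end_diastolic_diameter = num_or_na(lv_end_diastolic_diameter),
    lv_end_systolic_diameter = num_or_na(lv_end_systolic_diameter),
    lv_remodeling = as_tristate(lv_remodeling),
    rv_dysfunction = as_tristate(rv_dysfunction)
  ), class = "hlm_cardiac")
}

#' @param mpap_rest,mpap_exercise,pawp mmHg, or NA.
#' @param source provenance of the pressures: \code{"catheterization"},
#'   \code{"echo_estimate"} or \code{"unknown"}.
#' @rdname hlm_record
#' @export
hemodynamic_panel <- function(mpap_rest = NA, mpap_exercise = NA, pawp = NA,
                              source = "unknown") {
  source <- tolower(trimws(as.character(source)))
  if (is.na(source) || source == "") source <- "unknown"
  structure(list(mpap_rest = num_or_na(mpap_rest),
                 mpap_exercise = num_or_na(mpap_exercise),
                 pawp = num_or_na(pawp), source = source),
            class = "hlm_hemodynamics")
}

#' @param clinical_congestion_signs cardiopulmonary plus systemic signs and
#'   symptoms of congestion (tristate).
#' @param pulmonary_edema,pleural_effusion,cardiac_lung tristate flags.
#' @param abnormal_valsalva,orthostatic_bp_abnormal,nitroglycerin_response_abnormal
#'   bedside surrogates of elevated LV filling pressure (tristate).
#' @rdname hlm_record
#' @export
pulmonary_signs <- function(clinical_congestion_signs = "unknown",
                            pulmonary_edema = "unknown",
                            pleural_effusion = "unknown",
                            cardiac_lung = "unknown",
                            abnormal_valsalva = "unknown",
                            orthostatic_bp_abnormal = "unknown",
                            nitroglycerin_response_abnormal = "unknown") {
  structure(lapply(list(
    clinical_congestion_signs = clinical_congestion_signs,
    pulmonary_edema = pulmonary_edema,
    pleural_effusion = pleural_effusion,
    cardiac_lung = cardiac_lung,
    abnormal_valsalva = abnormal_valsalva,
    orthostatic_bp_abnormal = orthostatic_bp_abnormal,
    nitroglycerin_response_abnormal = nitroglycerin_response_abnormal
  ), as_tristate), class = "hlm_pulmonary")
}

#' @param serum_creatinine mg/dL, or NA.
#' @param bun blood urea nitrogen, mg/dL, or NA.
#' @param cystatin_c mg/L, or NA.
#' @param measured_clcr measured creatinine clearance, mL/min, or NA; when
#'   present it takes precedence over the Cockcroft-Gault estimate.
#' @rdname hlm_record
#' @export
renal_panel <- function(serum_creatinine = NA, bun = NA, cystatin_c = NA,
                        measured_clcr = NA) {
  structure(list(serum_creatinine = num_or_na(serum_creatinine),
                 bun = num_or_na(bun), cystatin_c = num_or_na(cystatin_c),
                 measured_clcr = num_or_na(measured_clcr)),
            class = "hlm_renal")
}

#' @param total_bilirubin_elevated,alt_elevated,ast_elevated,alp_elevated,ggt_elevated,albumin_decreased,inr_abnormal
#'   liver-lab abnormality flags (tristate).
#' @param on_anticoagulants logical; when TRUE the INR flag is excluded from
#'   liver-malfunction evidence (about a third of HF patients are
#'   anticoagulated, making INR uninterpretable as a liver test).
#' @param ascites,portal_flow_reduced,ivc_noncollapsing hemodynamic/structural
#'   hepatic congestion flags (tristate).
#' @rdname hlm_record
#' @export
hepatic_panel <- function(total_bilirubin_elevated = "unknown",
                          alt_elevated = "unknown",
                          ast_elevated = "unknown",
                          alp_elevated = "unknown",
                          ggt_elevated = "unknown",
                          albumin_decreased = "unknown",
                          inr_abnormal = "unknown",
                          on_anticoagulants = FALSE,
                          ascites = "unknown",
                          portal_flow_reduced = "unknown",
                          ivc_noncollapsing = "unknown") {
  out <- lapply(list(
    total_bilirubin_elevated = total_bilirubin_elevated,
    alt_elevated = alt_elevated, ast_elevated = ast_elevated,
    alp_elevated = alp_elevated, ggt_elevated = ggt_elevated,
    albumin_decreased = albumin_decreased, inr_abnormal = inr_abnormal,
    ascites = ascites, portal_flow_reduced = portal_flow_reduced,
    ivc_noncollapsing = ivc_noncollapsing
  ), as_tristate)
  out$on_anticoagulants <- isTRUE(on_anticoagulants)
  structure(out, class = "hlm_hepatic")
}

#' @param cerebral_hypoperfusion,depression tristate flags.
#' @rdname hlm_record
#' @export
neuro_panel <- function(cerebral_hypoperfusion = "unknown",
                        depression = "unknown") {
  structure(list(cerebral_hypoperfusion = as_tristate(cerebral_hypoperfusion),
                 depression = as_tristate(depression)),
            class = "hlm_neuro")
}

# ---- validation -----------------------------------------------------------

violation <- function(field, reason) {
  data.frame(field = field, reason = reason, stringsAsFactors = FALSE)
}

no_violations <- function() {
  data.frame(field = character(), reason = character(), stringsAsFactors = FALSE)
}

check_range <- function(x, field, lower = -Inf, upper = Inf,
                        strict_lower = FALSE) {
  if (is.na(x)) return(no_violations())
  bad_low <- if (strict_lower) x <= lower else x < lower
  if (bad_low || x > upper)
    violation(field, sprintf("value %g outside allowed range %s%g, %g]",
                             x, if (strict_lower) "(" else "[", lower, upper))
  else no_violations()
}

#' Validate an HLM patient record
#'
#' Checks every present field against its type invariants: ages at least 18
#' (adult heart-failure context), strictly positive weight/height/diameters
#' and renal measurements, ejection fraction in [0, 100], pressures in
#' [0, 120] mmHg, sex and previous-MI levels, and tristate levels. Missing
#' fields are legal and are not violations; the classifier accounts for them
#' through the completeness score instead.
#'
#' Violations are returned as data, not raised: a data frame with columns
#' \code{field} (dotted path into the record) and \code{reason}. The record
#' is never mutated, and validation is idempotent.
#'
#' @param record an \code{hlm_record}.
#' @return a data frame of violations; zero rows iff the record is valid.
#' @examples
#' d <- demographics(age = 60, sex = "male", weight = 80, height = 1.75)
#' nrow(validate_record(hlm_record("p1", d)))  # 0
#' @export
validate_record <- function(record) {
  stopifnot(inherits(record, "hlm_record"))
  v <- list(no_violations())
  d <- record$demographics
  if (is.na(d$age) || d$age < 18)
    v <- c(v, list(violation("demographics.age", "age must be >= 18 years")))
  else if (d$age != round(d$age))
    v <- c(v, list(violation("demographics.age", "age must be integer-valued years")))
  if (d$age >= 140 && !is.na(d$age))
    v <- c(v, list(violation("demographics.age", "age must be < 140 years")))
  if (!d$sex %in% c("female", "male"))
    v <- c(v, list(violation("demographics.sex", "sex must be 'female' or 'male'")))
  if (is.na(d$weight) || d$weight <= 0)
    v <- c(v, list(violation("demographics.weight", "weight (kg) must be > 0")))
  if (is.na(d$height) || d$height <= 0)
    v <- c(v, list(violation("demographics.height", "height (m) must be > 0")))

  ca <- record$cardiac
  v <- c(v, list(
    check_range(ca$ejection_fraction, "cardiac.ejection_fraction", 0, 100),
    check_range(ca$lv_end_diastolic_diameter, "cardiac.lv_end_diastolic_diameter",
                0, Inf, strict_lower = TRUE),
    check_range(ca$lv_end_systolic_diameter, "cardiac.lv_end_systolic_diameter",
                0, Inf, strict_lower = TRUE)
  ))
  if (!ca$previous_mi %in% c("none", "nstemi", "stemi", "unknown"))
    v <- c(v, list(violation("cardiac.previous_mi",
                             "must be one of none/nstemi/stemi/unknown")))

  he <- record$hemodynamics
  v <- c(v, list(
    check_range(he$mpap_rest, "hemodynamics.mpap_rest", 0, 120),
    check_range(he$mpap_exercise, "hemodynamics.mpap_exercise", 0, 120),
    check_range(he$pawp, "hemodynamics.pawp", 0, 120)
  ))
  if (!he$source %in% c("catheterization", "echo_estimate", "unknown"))
    v <- c(v, list(violation("hemodynamics.source",
                             "must be catheterization/echo_estimate/unknown")))

  re <- record$renal
  for (f in names(re)) {
    x <- re[[f]]
    if (!is.na(x) && x <= 0)
      v <- c(v, list(violation(paste0("renal.", f), "must be > 0 when present")))
  }

  for (panel in c("pulmonary", "hepatic", "neuro")) {
    p <- record[[panel]]
    for (f in names(p)) {
      x <- p[[f]]
      if (is.logical(x)) next  # on_anticoagulants
      if (!is_tristate(x))
        v <- c(v, list(violation(paste0(panel, ".", f),
                                 "must be present/absent/unknown")))
    }
  }
  for (f in c("systolic_dysfunction", "diastolic_dysfunction", "lv_hypertrophy",
              "lv_remodeling", "rv_dysfunction")) {
    if (!is_tristate(ca[[f]]))
      v <- c(v, list(violation(paste0("cardiac.", f),
                               "must be present/absent/unknown")))
  }
  do.call(rbind, v)
}

#' @export
print.hlm_record <- function(x, ...) {
  cat("HLM patient record", x$patient_id, "\n")
  d <- x$demographics
  cat(sprintf("  %s, %g y, %.1f kg, %.2f m%s\n", d$sex, d$age, d$weight,
              d$height, if (d$black_ethnicity) ", black" else ""))
  invisible(x)
}
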