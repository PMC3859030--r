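#' Classify pulmonary-hypertension type from right-heart hemodynamics
#'
#' Pulmonary hypertension (PH) is present when resting mean pulmonary
#' arterial pressure exceeds 25 mmHg (strict). When no resting value is
#' available, an exercise value above 30 mmHg substitutes (normal is below
#' 25 at rest and below 30 during exercise); when a resting value exists it
#' always decides, even if an exercise value disagrees. Among PH-present
#' patients the wedge pressure splits the type: PAWP <= 15 mmHg is
#' precapillary (boundary inclusive), PAWP > 15 mmHg postcapillary. PH
#' present without a wedge pressure, or no usable mPAP at all, returns
#' \code{"unknown"}.
#'
#' @param hemo a \code{\link{hemodynamic_panel}}.
#' @param config an \code{\link{hlm_config}}.
#' @return one of \code{"none"}, \code{"precapillary"},
#'   \code{"postcapillary"}, \code{"unknown"}.
#' @examples
#' classify_ph(hemodynamic_panel(mpap_rest = 30, pawp = 20))  # postcapillary
#' classify_ph(hemodynamic_panel(mpap_rest = 30, pawp = 15))  # precapillary
#' classify_ph(hemodynamic_panel(mpap_rest = 25, pawp = 10))  # none
#' @export
classify_ph <- function(hemo, config = hlm_config()) {
  if (!is.na(hemo$mpap_rest)) {
    ph <- hemo$mpap_rest > config$mpap_rest_cutoff
  } else if (!is.na(hemo$mpap_exercise)) {
    ph <- hemo$mpap_exercise > config$mpap_exercise_cutoff
  } else {
    return("unknown")
  }
  if (!ph) return("none")
  if (is.na(hemo$pawp)) return("unknown")
  if (hemo$pawp <= config$pawp_cutoff) "precapillary" else "postcapillary"
}

#' Derive pulmonary findings for the L ladder
#'
#' Bundles the hemodynamic classification with the clinical-sign flags.
#' Clinical congestion is forced present whenever pulmonary edema is
#' present (edema is the florid form of clinical congestion); pleural
#' effusion counts as clinical-congestion evidence by default
#' (\code{pleural_effusion_is_clinical}), otherwise as hemodynamic
#' evidence. Hemodynamic congestion evidence is postcapillary PH (and,
#' by default, precapillary PH -- \code{precapillary_counts_hemodynamic})
#' or any abnormal bedside filling-pressure surrogate (Valsalva maneuver,
#' orthostatic blood-pressure response, nitroglycerin response).
#'
#' @param signs a \code{\link{pulmonary_signs}} panel.
#' @param ph a PH type from \code{\link{classify_ph}}.
#' @param config an \code{\link{hlm_config}}.
#' @return a list of class \code{hlm_pulmonary_findings}: \code{ph_type},
#'   tristates \code{hemodynamic_congestion}, \code{clinical_congestion},
#'   \code{cardiac_lung}, \code{pulmonary_edema}.
#' @export
derive_pulmonary_findings <- function(signs, ph, config = hlm_config()) {
  clinical <- tri_or(signs$clinical_congestion_signs, signs$pulmonary_edema,
                     if (config$pleural_effusion_is_clinical)
                       signs$pleural_effusion else "absent")

  bedside <- tri_or(signs$abnormal_valsalva, signs$orthostatic_bp_abnormal,
                    signs$nitroglycerin_response_abnormal)
  ph_hemo <- if (ph == "postcapillary" ||
                 (ph == "precapillary" && config$precapillary_counts_hemodynamic))
    "present" else if (ph == "unknown") "unknown" else "absent"
  pleural_hemo <- if (config$pleural_effusion_is_clinical) "absent"
                  else signs$pleural_effusion
  hemodynamic <- tri_or(ph_hemo, bedside, pleural_hemo)

  structure(list(
    ph_type = ph,
    hemodynamic_congestion = hemodynamic,
    clinical_congestion = clinical,
    cardiac_lung = signs$cardiac_lung,
    pulmonary_edema = signs$pulmonary_edema
  ), class = "hlm_pulmonary_findings")
}

#' Assign the Lung (L) stage
#'
#' The L ladder, highest satisfied rule wins:
#' \itemize{
#'   \item L3: cardiac lung (arterialization of the pulmonary vasculature).
#'   \item L2: clinical congestion -- cardiopulmonary and systemic signs and
#'     symptoms; pulmonary edema always classifies here at minimum.
#'   \item L1: hemodynamic congestion -- elevated filling pressures
#'     (postcapillary PH, or bedside surrogates) without clinical signs.
#'   \item L0: no evidence of pulmonary involvement. L0 is a package
#'     extension: the published ladder starts at L1 and leaves the
#'     no-involvement case undefined.
#' }
#' Unknown flags never satisfy a rule.
#'
#' @param signs a \code{\link{pulmonary_signs}} panel.
#' @param ph a PH type from \code{\link{classify_ph}}.
#' @param config an \code{\link{hlm_config}}.
#' @return integer 0--3.
#' @examples
#' s <- pulmonary_signs(pulmonary_edema = "present", cardiac_lung = "absent")
#' stage_l(s, ph = "none")  # 2
#' @export
stage_l <- function(signs, ph, config = hlm_config()) {
  f <- derive_pulmonary_findings(signs, ph, config)
  stage_l_findings(f)
}

# ladder over derived findings (shared with the truth-table tests)
stage_l_findings <- function(f) {
  p <- function(x) identical(x, "present")
  if (p(f$cardiac_lung)) return(3L)
  if (p(f$clinical_congestion)) return(2L)
  if (p(f$hemodynamic_congestion)) return(1L)
  0L
}
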