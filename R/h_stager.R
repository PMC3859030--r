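#' Derive cardiac criterion findings from an echo/history panel
#'
#' Collapses the raw cardiac panel into the six tristate criteria the H
#' ladder is written in:
#' \itemize{
#'   \item \code{systolic_dysfunction}: the adjudicated flag; when unknown
#'     and an ejection fraction is available, auto-derived as EF below the
#'     configurable 50\% cutoff (a package default, not a published one).
#'   \item \code{diastolic_dysfunction}: the adjudicated (transmitral-flow
#'     based) flag, taken as given.
#'   \item \code{structural_damage}: hypertrophy OR a previous myocardial
#'     infarction (NSTEMI or STEMI).
#'   \item \code{remodeling}: the adjudicated flag; when unknown, inferred
#'     present if either LV diameter exceeds the upper bound of its
#'     reference band, absent if diameters are available and within.
#'   \item \code{severe_ef}: EF strictly below the severe cutoff (35\%).
#'   \item \code{biventricular}: right-ventricular dysfunction together with
#'     LV (systolic or diastolic) dysfunction.
#' }
#' Unknown inputs propagate to unknown findings; nothing is imputed.
#'
#' @param cardiac a \code{\link{cardiac_panel}}.
#' @param config an \code{\link{hlm_config}}.
#' @return a list of class \code{hlm_cardiac_findings} of six tristates.
#' @export
derive_cardiac_findings <- function(cardiac, config = hlm_config()) {
  ef <- cardiac$ejection_fraction

  sys <- cardiac$systolic_dysfunction
  if (sys == "unknown" && !is.na(ef))
    sys <- if (ef < config$ef_systolic_dysfunction_cutoff) "present" else "absent"

  dia <- cardiac$diastolic_dysfunction

  mi <- switch(cardiac$previous_mi,
               none = "absent", nstemi = "present", stemi = "present",
               "unknown")
  structural <- tri_or(cardiac$lv_hypertrophy, mi)

  severe <- if (is.na(ef)) "unknown"
            else if (ef < config$ef_severe_cutoff) "present" else "absent"

  remodeling <- cardiac$lv_remodeling
  if (remodeling == "unknown") {
    dd <- cardiac$lv_end_diastolic_diameter
    sd <- cardiac$lv_end_systolic_diameter
    dil_dd <- if (is.na(dd)) "unknown"
              else if (dd > diam_upper(config$lvdd_normal)) "present" else "absent"
    dil_sd <- if (is.na(sd)) "unknown"
              else if (sd > diam_upper(config$lvsd_normal)) "present" else "absent"
    if (!is.na(dd) || !is.na(sd)) remodeling <- tri_or(dil_dd, dil_sd)
    # tri_or of one known "absent" and one unknown is unknown: correct,
    # the unmeasured diameter could still be dilated.
  }

  biv <- tri_and(cardiac$rv_dysfunction, tri_or(sys, dia))

  structure(list(
    systolic_dysfunction = sys,
    diastolic_dysfunction = dia,
    structural_damage = structural,
    remodeling = remodeling,
    severe_ef = severe,
    biventricular = biv
  ), class = "hlm_cardiac_findings")
}

#' Assign the Heart (H) stage
#'
#' The H ladder, highest satisfied rule wins (evaluated H4 down to H1):
#' \itemize{
#'   \item H4: biventricular dysfunction.
#'   \item H3: left-ventricular remodeling together with combined systolic
#'     and diastolic dysfunction and/or severe ejection fraction (< 35\%).
#'   \item H2: systolic or diastolic dysfunction with structural damage
#'     (hypertrophy or previous myocardial infarction).
#'   \item H1: systolic or diastolic dysfunction without structural damage.
#' }
#' Severe ejection fraction counts as systolic-dysfunction evidence on the
#' H1/H2 rungs, so a severely reduced EF is never left unstaged. A criterion
#' that is unknown never satisfies a rule; with no dysfunction evidence at
#' all the patient is \code{not_stageable} (\code{NA}) -- the ladder starts
#' at H1 and the engine does not invent an H0.
#'
#' @param findings an \code{hlm_cardiac_findings} from
#'   \code{\link{derive_cardiac_findings}}.
#' @return integer 1--4, or \code{NA_integer_} for not stageable.
#' @export
stage_h <- function(findings) {
  p <- function(x) identical(x, "present")
  dysfunction <- p(findings$systolic_dysfunction) ||
    p(findings$diastolic_dysfunction) || p(findings$severe_ef)
  if (p(findings$biventricular)) return(4L)
  if (p(findings$remodeling) &&
      ((p(findings$systolic_dysfunction) && p(findings$diastolic_dysfunction)) ||
        p(findings$severe_ef))) return(3L)
  if (dysfunction && p(findings$structural_damage)) return(2L)
  if (dysfunction) return(1L)
  NA_integer_
}
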