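#' Per-organ malfunction status
#'
#' Internal constructor for the kidney/liver/brain assessments: a tristate
#' \code{malfunction}, the fired criteria as \code{evidence}, supportive
#' (non-firing) observations as \code{supportive}, and the HF-attribution
#' tristate (defaults to unknown, which is counted -- the engine cannot
#' adjudicate etiology and excluding unknowns would systematically
#' understage).
#'
#' @noRd
organ_status <- function(organ, malfunction, evidence = character(),
                         supportive = character(),
                         attributable_to_hf = "unknown") {
  stopifnot(is_tristate(malfunction))
  if (malfunction == "present" && length(evidence) == 0L)
    stop("malfunction present requires evidence", call. = FALSE)
  structure(list(organ = organ, malfunction = malfunction,
                 evidence = evidence, supportive = supportive,
                 attributable_to_hf = as_tristate(attributable_to_hf)),
            class = "hlm_organ_status")
}

#' Assess kidney malfunction
#'
#' The kidney counts as malfunctioning when the creatinine clearance
#' (measured if available, else Cockcroft-Gault) falls below its
#' sex-specific reference interval, when the simplified-MDRD GFR is below
#' the malfunction cutoff (default 60 mL/min/1.73m2), or when cystatin C is
#' elevated. An elevated blood urea nitrogen alone never fires -- BUN is an
#' ambiguous marker, strongly influenced by catabolism -- and is recorded
#' as supportive evidence only. Likewise an abnormal serum creatinine with
#' normal clearance does not fire: creatinine alone is not a reliable
#' measure of renal function (it tracks muscle mass). The status is unknown
#' when every renal determinant is unavailable.
#'
#' @param derived an \code{hlm_derived} from
#'   \code{\link{flag_reference_ranges}}.
#' @param config an \code{\link{hlm_config}}.
#' @param attributable_to_hf tristate attribution of the damage to heart
#'   failure; unknown counts toward the M score.
#' @return an \code{hlm_organ_status}.
#' @export
assess_kidney <- function(derived, config = hlm_config(),
                          attributable_to_hf = "unknown") {
  evidence <- character()
  if (derived$clcr_flag == "below")
    evidence <- c(evidence, sprintf("creatinine clearance %.1f mL/min below reference (%s)",
                                    derived$clcr_used, derived$clcr_source))
  if (!is.na(derived$gfr_smdrd) && derived$gfr_smdrd < config$gfr_malfunction_cutoff)
    evidence <- c(evidence, sprintf("sMDRD GFR %.1f below %g mL/min/1.73m2",
                                    derived$gfr_smdrd, config$gfr_malfunction_cutoff))
  if (derived$cystatin_flag == "above")
    evidence <- c(evidence, "cystatin C elevated [non-paper threshold]")

  supportive <- character()
  if (derived$bun_flag == "above")
    supportive <- c(supportive, "BUN elevated (ambiguous marker, supportive only)")
  if (derived$scr_flag == "above")
    supportive <- c(supportive, "serum creatinine above reference")

  known <- derived$clcr_flag != "unknown" ||
    !is.na(derived$gfr_smdrd) || derived$cystatin_flag != "unknown"
  malfunction <- if (length(evidence)) "present"
                 else if (known) "absent" else "unknown"
  organ_status("kidney", malfunction, evidence, supportive, attributable_to_hf)
}

#' Assess liver malfunction
#'
#' Liver function tests are aspecific: staging hepatic damage on a single
#' lab would be simplistic and misleading, so at least
#' \code{liver_min_abnormal_labs} (default 2) abnormal labs are required
#' among \{total bilirubin elevated, ALT elevated, AST elevated, alkaline
#' phosphatase elevated, gamma-GT elevated, albumin decreased, INR
#' abnormal\}. The INR is excluded from the tally when the patient is
#' anticoagulated. Hemodynamic/structural evidence of hepatic congestion
#' (ascites, reduced portal flow, a non-collapsing inferior vena cava)
#' fires on its own. Unknown flags count as absent in the tally; the
#' status is unknown only when every flag is unknown.
#'
#' @param hepatic a \code{\link{hepatic_panel}}.
#' @param config an \code{\link{hlm_config}}.
#' @param attributable_to_hf tristate attribution.
#' @return an \code{hlm_organ_status}.
#' @export
assess_liver <- function(hepatic, config = hlm_config(),
                         attributable_to_hf = "unknown") {
  labs <- c(total_bilirubin_elevated = hepatic$total_bilirubin_elevated,
            alt_elevated = hepatic$alt_elevated,
            ast_elevated = hepatic$ast_elevated,
            alp_elevated = hepatic$alp_elevated,
            ggt_elevated = hepatic$ggt_elevated,
            albumin_decreased = hepatic$albumin_decreased,
            inr_abnormal = hepatic$inr_abnormal)
  inr_excluded <- isTRUE(hepatic$on_anticoagulants)
  tally_labs <- if (inr_excluded) labs[names(labs) != "inr_abnormal"] else labs
  n_abnormal <- sum(tally_labs == "present")

  struct <- c(ascites = hepatic$ascites,
              portal_flow_reduced = hepatic$portal_flow_reduced,
              ivc_noncollapsing = hepatic$ivc_noncollapsing)

  evidence <- character()
  if (n_abnormal >= config$liver_min_abnormal_labs)
    evidence <- c(evidence, sprintf("%d abnormal liver labs (>= %d): %s",
                                    n_abnormal, config$liver_min_abnormal_labs,
                                    paste(names(tally_labs)[tally_labs == "present"],
                                          collapse = ", ")))
  fired_struct <- names(struct)[struct == "present"]
  if (length(fired_struct))
    evidence <- c(evidence, paste("hepatic congestion evidence:",
                                  paste(fired_struct, collapse = ", ")))

  supportive <- character()
  if (n_abnormal > 0 && n_abnormal < config$liver_min_abnormal_labs)
    supportive <- c(supportive,
                    sprintf("%d abnormal liver lab(s), below the %d-lab rule",
                            n_abnormal, config$liver_min_abnormal_labs))
  if (inr_excluded && hepatic$inr_abnormal == "present")
    supportive <- c(supportive, "INR abnormal but patient anticoagulated (excluded)")

  all_flags <- c(labs, struct)
  all_unknown <- all(all_flags == "unknown")
  malfunction <- if (length(evidence)) "present"
                 else if (all_unknown) "unknown" else "absent"
  organ_status("liver", malfunction, evidence, supportive, attributable_to_hf)
}

#' Assess brain malfunction
#'
#' Cerebral involvement in heart failure: cerebral hypoperfusion (impaired
#' cerebral function / vasoreactivity) or depression, either of which
#' fires. Unknown only when both flags are unknown.
#'
#' @param neuro a \code{\link{neuro_panel}}.
#' @param attributable_to_hf tristate attribution.
#' @return an \code{hlm_organ_status}.
#' @export
assess_brain <- function(neuro, attributable_to_hf = "unknown") {
  evidence <- character()
  if (neuro$cerebral_hypoperfusion == "present")
    evidence <- c(evidence, "cerebral hypoperfusion")
  if (neuro$depression == "present")
    evidence <- c(evidence, "depression")
  malfunction <- tri_or(neuro$cerebral_hypoperfusion, neuro$depression)
  # tri_or gives unknown when one flag is unknown and the other absent;
  # the ladder wants a definite "absent" there (no positive evidence, some
  # assessment done) and unknown only when nothing was assessed.
  if (malfunction == "unknown" &&
      !(neuro$cerebral_hypoperfusion == "unknown" && neuro$depression == "unknown"))
    malfunction <- "absent"
  organ_status("brain", malfunction, evidence,
               attributable_to_hf = attributable_to_hf)
}

#' Assign the Malfunction-of-other-organs (M) stage
#'
#' Counts the organs whose malfunction is present and not positively
#' attributed away from heart failure (attribution absent excludes the
#' organ; unknown counts). The count maps 0 / 1 / 2 / >= 3 to M0 / M1 /
#' M2 / M3. With the three-organ model the count cannot exceed 3, but the
#' mapping implements the open-ended rule so additional organs need no
#' logic change.
#'
#' @param statuses a list of \code{hlm_organ_status}, one per distinct
#'   organ.
#' @return integer 0--3.
#' @examples
#' k <- assess_kidney(flag_reference_ranges(
#'   renal_panel(serum_creatinine = 2.5),
#'   demographics(70, "male", 80, 1.75)))
#' stage_m(list(k))  # 1
#' @export
stage_m <- function(statuses) {
  organs <- vapply(statuses, function(s) s$organ, character(1))
  if (anyDuplicated(organs))
    stop("duplicate organ entries: ", paste(organs[duplicated(organs)],
                                            collapse = ", "), call. = FALSE)
  counted <- vapply(statuses, function(s)
    s$malfunction == "present" && s$attributable_to_hf != "absent", logical(1))
  n <- sum(counted)
  if (n >= 3L) 3L else as.integer(n)
}
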