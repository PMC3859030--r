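# Fields whose observation counts toward the completeness score: the
# inputs the three stage engines actually consume. Demographics are
# mandatory (validated) and not counted.
required_fields <- list(
  cardiac = c("ejection_fraction", "systolic_dysfunction",
              "diastolic_dysfunction", "lv_hypertrophy", "previous_mi",
              "lv_remodeling", "rv_dysfunction"),
  hemodynamics = c("mpap_rest", "pawp"),
  pulmonary = c("clinical_congestion_signs", "pulmonary_edema",
                "pleural_effusion", "cardiac_lung", "abnormal_valsalva",
                "orthostatic_bp_abnormal", "nitroglycerin_response_abnormal"),
  renal = c("serum_creatinine", "cystatin_c"),
  hepatic = c("total_bilirubin_elevated", "alt_elevated", "ast_elevated",
              "alp_elevated", "ggt_elevated", "albumin_decreased",
              "inr_abnormal", "ascites", "portal_flow_reduced",
              "ivc_noncollapsing"),
  neuro = c("cerebral_hypoperfusion", "depression")
)

field_observed <- function(x) {
  if (is.numeric(x)) !is.na(x)
  else !identical(x, "unknown")
}

completeness_score <- function(record) {
  obs <- 0L; tot <- 0L
  for (panel in names(required_fields)) {
    for (f in required_fields[[panel]]) {
      tot <- tot + 1L
      if (field_observed(record[[panel]][[f]])) obs <- obs + 1L
    }
  }
  obs / tot
}

#' Format and parse HLM staging codes
#'
#' The combined code concatenates the three components as
#' \code{"H{h}L{l}M{m}"}, e.g. \code{"H1L1M0"} for initial-stage disease or
#' \code{"H4L3M3"} for true end-stage disease. A cardiac component that
#' could not be staged renders as \code{"H?"}. Parsing accepts codes
#' case-insensitively, requires H in 1--4 (or \code{?}), L and M in 0--3,
#' and reports the position of the first offending character otherwise.
#' \code{format_hlm_code(parse_hlm_code(x))} normalises any valid code.
#'
#' @param h,l,m stage components; \code{h} may be \code{NA} (not stageable).
#' @param code a code string such as \code{"H2L2M1"}.
#' @return \code{format_hlm_code}: the code string. \code{parse_hlm_code}:
#'   a named list \code{list(h =, l =, m =)} of integers, \code{h} possibly
#'   \code{NA}.
#' @examples
#' parse_hlm_code("h4l3m3")
#' format_hlm_code(2, 2, 1)
#' @export
format_hlm_code <- function(h, l, m) {
  stopifnot(is.na(h) || h %in% 1:4, l %in% 0:3, m %in% 0:3)
  sprintf("H%sL%dM%d", if (is.na(h)) "?" else as.character(as.integer(h)),
          as.integer(l), as.integer(m))
}

#' @rdname format_hlm_code
#' @export
parse_hlm_code <- function(code) {
  stopifnot(is.character(code), length(code) == 1L)
  m <- regexec("^[Hh]([1-4?])[Ll]([0-3])[Mm]([0-3])$", code)[[1]]
  if (m[1] == -1L) {
    # locate the first position where the pattern breaks, for the message
    expected <- c("H", "1-4 or ?", "L", "0-3", "M", "0-3")
    chars <- strsplit(code, "")[[1]]
    ok <- c(grepl("^[Hh]$", chars[1] %||% ""),
            grepl("^[1-4?]$", chars[2] %||% ""),
            grepl("^[Ll]$", chars[3] %||% ""),
            grepl("^[0-3]$", chars[4] %||% ""),
            grepl("^[Mm]$", chars[5] %||% ""),
            grepl("^[0-3]$", chars[6] %||% ""))
    pos <- which(!ok)[1]
    if (is.na(pos)) pos <- 7L  # all six fine, trailing junk
    stop(sprintf("malformed HLM code '%s' at position %d (expected %s)",
                 code, pos, if (pos <= 6) expected[pos] else "end of code"),
         call. = FALSE)
  }
  parts <- regmatches(code, regexec("^[Hh]([1-4?])[Ll]([0-3])[Mm]([0-3])$",
                                    code))[[1]][-1]
  list(h = if (parts[1] == "?") NA_integer_ else as.integer(parts[1]),
       l = as.integer(parts[2]), m = as.integer(parts[3]))
}

`%||%` <- function(a, b)
  if (is.null(a) || (length(a) == 1L && is.na(a))) b else a

prov_row <- function(criterion, value, fired, note = "") {
  data.frame(criterion = criterion, value = as.character(value),
             fired = fired, note = note, stringsAsFactors = FALSE)
}

#' Stage a patient record on the HLM ladder
#'
#' Runs the full pipeline: cardiac findings to the H stage,
#' pulmonary-hypertension classification and congestion signs to the L
#' stage, derived renal measures and the three organ assessments to the M
#' stage; assembles the combined code, a per-criterion provenance table,
#' and a data-completeness score. The classifier never imputes: unknown
#' inputs lower completeness and leave conservative (lower) stages rather
#' than guessed ones.
#'
#' @param record an \code{\link{hlm_record}}; it must pass
#'   \code{\link{validate_record}}, otherwise classification is refused
#'   with every violation listed.
#' @param config an \code{\link{hlm_config}}.
#' @param attribution optional named tristates
#'   (\code{kidney}, \code{liver}, \code{brain}) stating whether each
#'   organ's damage is attributable to heart failure; unknown (the
#'   default) counts toward M.
#' @return an object of class \code{hlm_result} with elements
#'   \code{patient_id}, \code{h_stage} (1--4 or NA), \code{l_stage} (0--3),
#'   \code{m_stage} (0--3), \code{malfunctioning_organs}, \code{code},
#'   \code{provenance} (data frame: criterion, value, fired, note),
#'   \code{completeness}, \code{notes}, plus the intermediate
#'   \code{findings}, \code{derived} and \code{organ_statuses}.
#' @examples
#' rec <- hlm_record("p1",
#'   demographics(60, "male", 80, 1.75),
#'   cardiac = cardiac_panel(systolic_dysfunction = "absent",
#'                           diastolic_dysfunction = "present",
#'                           lv_hypertrophy = "absent", previous_mi = "none",
#'                           lv_remodeling = "absent", rv_dysfunction = "absent"))
#' classify(rec)$code
#' @export
classify <- function(record, config = hlm_config(), attribution = list()) {
  viol <- validate_record(record)
  if (nrow(viol) > 0L)
    stop("record ", record$patient_id, " fails validation:\n",
         paste(sprintf("  - %s: %s", viol$field, viol$reason), collapse = "\n"),
         call. = FALSE)
  attr_of <- function(organ) as_tristate(attribution[[organ]] %||% "unknown")

  # H
  findings <- derive_cardiac_findings(record$cardiac, config)
  h <- stage_h(findings)

  # L
  ph <- classify_ph(record$hemodynamics, config)
  pf <- derive_pulmonary_findings(record$pulmonary, ph, config)
  l <- stage_l_findings(pf)

  # M
  derived <- flag_reference_ranges(record$renal, record$demographics,
                                   record$cardiac, config)
  statuses <- list(
    kidney = assess_kidney(derived, config, attr_of("kidney")),
    liver  = assess_liver(record$hepatic, config, attr_of("liver")),
    brain  = assess_brain(record$neuro, attr_of("brain"))
  )
  m <- stage_m(statuses)
  organs <- names(statuses)[vapply(statuses, function(s)
    s$malfunction == "present" && s$attributable_to_hf != "absent", logical(1))]

  prov <- rbind(
    prov_row("h.systolic_dysfunction", findings$systolic_dysfunction,
             findings$systolic_dysfunction == "present"),
    prov_row("h.diastolic_dysfunction", findings$diastolic_dysfunction,
             findings$diastolic_dysfunction == "present"),
    prov_row("h.structural_damage", findings$structural_damage,
             findings$structural_damage == "present",
             "hypertrophy or previous MI"),
    prov_row("h.remodeling", findings$remodeling,
             findings$remodeling == "present",
             "reference diameters: end-diastolic 50+/-5 mm, end-systolic 31+/-5 mm (printed order in the source pairs 50 with 'systolic'; clinical convention adopted)"),
    prov_row("h.severe_ef", findings$severe_ef,
             findings$severe_ef == "present",
             sprintf("EF < %g%% (strict)", config$ef_severe_cutoff)),
    prov_row("h.biventricular", findings$biventricular,
             findings$biventricular == "present"),
    prov_row("l.ph_type", ph, ph %in% c("precapillary", "postcapillary"),
             sprintf("mPAP > %g mmHg rest (> %g exercise); PAWP <= %g precapillary",
                     config$mpap_rest_cutoff, config$mpap_exercise_cutoff,
                     config$pawp_cutoff)),
    prov_row("l.hemodynamic_congestion", pf$hemodynamic_congestion,
             pf$hemodynamic_congestion == "present"),
    prov_row("l.clinical_congestion", pf$clinical_congestion,
             pf$clinical_congestion == "present"),
    prov_row("l.cardiac_lung", pf$cardiac_lung, pf$cardiac_lung == "present"),
    prov_row("m.kidney", statuses$kidney$malfunction,
             statuses$kidney$malfunction == "present",
             paste(c(statuses$kidney$evidence, statuses$kidney$supportive),
                   collapse = "; ")),
    prov_row("m.liver", statuses$liver$malfunction,
             statuses$liver$malfunction == "present",
             paste(c(statuses$liver$evidence, statuses$liver$supportive),
                   collapse = "; ")),
    prov_row("m.brain", statuses$brain$malfunction,
             statuses$brain$malfunction == "present",
             paste(statuses$brain$evidence, collapse = "; "))
  )

  completeness <- completeness_score(record)
  notes <- character()
  if (completeness == 0)
    notes <- c(notes, "no clinical fields observed: staging is vacuous")
  if (is.na(h))
    notes <- c(notes, "H not stageable: no LV dysfunction evidence (ladder starts at H1)")
  if (l == 0L)
    notes <- c(notes, "L0 is a package extension: no pulmonary involvement evidence (published ladder starts at L1)")
  cardiac_involved <- !is.na(h) ||
    findings$severe_ef == "present" || findings$structural_damage == "present"
  if (cardiac_involved && statuses$kidney$malfunction == "present")
    notes <- c(notes, "cardiac and renal findings coexist: consistent with a cardiorenal syndrome (descriptive note only)")
  if (!is.na(derived$bmi) && isTRUE(config$count_cachexia_as_organ) &&
      !is.na(config$cachexia_bmi_cutoff) &&
      derived$bmi < config$cachexia_bmi_cutoff)
    notes <- c(notes, sprintf("BMI %.1f below cachexia cutoff %.1f: severity note (cachexia reflects multiorgan failure)",
                              derived$bmi, config$cachexia_bmi_cutoff))
  notes <- c(notes, therapy_note(h, l, m))

  structure(list(
    patient_id = record$patient_id,
    h_stage = h, l_stage = l, m_stage = m,
    malfunctioning_organs = organs,
    code = format_hlm_code(h, l, m),
    provenance = prov,
    completeness = completeness,
    notes = notes,
    findings = findings,
    ph_type = ph,
    pulmonary_findings = pf,
    derived = derived,
    organ_statuses = statuses
  ), class = "hlm_result")
}

# descriptive therapy-tier orientation; no treatment logic
therapy_note <- function(h, l, m) {
  if (!is.na(h) && h >= 4 && l >= 3 && m >= 3)
    "orientation: true end-stage pattern; palliative support targeting quality of life (descriptive only)"
  else if (!is.na(h) && h >= 2 && l >= 2)
    "orientation: second-tier therapies with organ-protective cover (descriptive only)"
  else if (!is.na(h) && h == 1 && l <= 1 && m == 0)
    "orientation: initial-stage pattern; traditional therapy (descriptive only)"
  else
    "orientation: intermediate pattern (descriptive only)"
}

#' @export
print.hlm_result <- function(x, ...) {
  cat(sprintf("HLM stage for %s: %s  (completeness %.0f%%)\n",
              x$patient_id, x$code, 100 * x$completeness))
  if (length(x$malfunctioning_organs))
    cat("  malfunctioning organs:",
        paste(x$malfunctioning_organs, collapse = ", "), "\n")
  fired <- x$provenance[x$provenance$fired, "criterion"]
  if (length(fired)) cat("  fired criteria:", paste(fired, collapse = ", "), "\n")
  for (n in x$notes) cat("  note:", n, "\n")
  invisible(x)
}

#' Stage a whole cohort
#'
#' Applies \code{\link{classify}} to each record and returns one row per
#' patient. Records that fail validation are reported in the
#' \code{error} column instead of aborting the batch.
#'
#' @param records a list of \code{\link{hlm_record}}s.
#' @param config an \code{\link{hlm_config}}.
#' @return a data frame with columns \code{patient_id}, \code{h_stage},
#'   \code{l_stage}, \code{m_stage}, \code{code},
#'   \code{malfunctioning_organs} (comma-separated), \code{completeness},
#'   \code{error}.
#' @export
classify_cohort <- function(records, config = hlm_config()) {
  rows <- lapply(records, function(rec) {
    res <- tryCatch(classify(rec, config), error = function(e) e)
    if (inherits(res, "error")) {
      data.frame(patient_id = rec$patient_id, h_stage = NA_integer_,
                 l_stage = NA_integer_, m_stage = NA_integer_,
                 code = NA_character_, malfunctioning_organs = NA_character_,
                 completeness = NA_real_, error = conditionMessage(res),
                 stringsAsFactors = FALSE)
    } else {
      data.frame(patient_id = res$patient_id, h_stage = res$h_stage,
                 l_stage = res$l_stage, m_stage = res$m_stage,
                 code = res$code,
                 malfunctioning_organs = paste(res$malfunctioning_organs,
                                               collapse = ";"),
                 completeness = res$completeness, error = "",
                 stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, rows)
}
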