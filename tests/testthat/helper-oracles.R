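# Independent brute-force oracles, coded as direct transcriptions of the
# published decision tables (separately from the package's derivation
# pipeline), plus small search utilities shared by the tests and used to
# freeze expected values.

TRI <- c("present", "absent", "unknown")

# H ladder transcription over the six derived criteria
oracle_stage_h <- function(sys, dia, struct, rem, sev, biv) {
  P <- function(x) x == "present"
  dysfunction <- P(sys) || P(dia) || P(sev)
  if (P(biv)) return(4L)
  if (P(rem) && ((P(sys) && P(dia)) || P(sev))) return(3L)
  if (dysfunction && P(struct)) return(2L)
  if (dysfunction) return(1L)
  NA_integer_
}

# L ladder transcription over raw signs + PH type, with the default config
# semantics (pleural effusion = clinical evidence, precapillary = L1)
oracle_stage_l <- function(signs, ph) {
  P <- function(x) x == "present"
  if (P(signs$cardiac_lung)) return(3L)
  if (P(signs$clinical_congestion_signs) || P(signs$pulmonary_edema) ||
      P(signs$pleural_effusion)) return(2L)
  if (ph %in% c("precapillary", "postcapillary") ||
      P(signs$abnormal_valsalva) || P(signs$orthostatic_bp_abnormal) ||
      P(signs$nitroglycerin_response_abnormal)) return(1L)
  0L
}

# M: counting transcription
oracle_stage_m <- function(statuses) {
  n <- sum(vapply(statuses, function(s)
    s$malfunction == "present" && s$attributable_to_hf != "absent",
    logical(1)))
  min(n, 3L)
}

# renal formulas on an independent numerical path (log-space)
oracle_cg <- function(scr, age, weight, sex) {
  v <- exp(log(140 - age) + log(weight) - log(72) - log(scr))
  if (sex == "female") v * 0.85 else v
}
oracle_smdrd <- function(scr, age, sex, black) {
  exp(log(186) - 1.154 * log(scr) - 0.203 * log(age) +
        ifelse(sex == "female", log(0.742), 0) + ifelse(black, log(1.21), 0))
}

# all 3^k tristate combinations as a data frame of characters
tristate_grid <- function(fields) {
  g <- do.call(expand.grid, c(stats::setNames(
    rep(list(TRI), length(fields)), fields), stringsAsFactors = FALSE))
  g
}

# find, by bisection, the boundary point of a monotone predicate
# f: numeric -> logical, FALSE below the boundary, TRUE above
bisect_boundary <- function(f, lo, hi, tol = 1e-9) {
  stopifnot(!f(lo), f(hi))
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (f(mid)) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}

# a fully specified, valid record with every panel normal
complete_normal_record <- function(id = "ref") {
  hlm_record(id,
    demographics(60, "male", 80, 1.75),
    cardiac = cardiac_panel(
      ejection_fraction = 60, systolic_dysfunction = "absent",
      diastolic_dysfunction = "absent", lv_hypertrophy = "absent",
      previous_mi = "none", lv_end_diastolic_diameter = 50,
      lv_end_systolic_diameter = 31, lv_remodeling = "absent",
      rv_dysfunction = "absent"),
    hemodynamics = hemodynamic_panel(mpap_rest = 18, pawp = 10,
                                     source = "catheterization"),
    pulmonary = pulmonary_signs(
      clinical_congestion_signs = "absent", pulmonary_edema = "absent",
      pleural_effusion = "absent", cardiac_lung = "absent",
      abnormal_valsalva = "absent", orthostatic_bp_abnormal = "absent",
      nitroglycerin_response_abnormal = "absent"),
    # scr 0.85: Cockcroft-Gault (140-60)*80/(72*0.85) = 104.6, inside the
    # male 95-145 band; sMDRD 97.7, clear of the 60 cutoff
    renal = renal_panel(serum_creatinine = 0.85, bun = 15, cystatin_c = 0.8),
    hepatic = hepatic_panel(
      total_bilirubin_elevated = "absent", alt_elevated = "absent",
      ast_elevated = "absent", alp_elevated = "absent",
      ggt_elevated = "absent", albumin_decreased = "absent",
      inr_abnormal = "absent", on_anticoagulants = FALSE,
      ascites = "absent", portal_flow_reduced = "absent",
      ivc_noncollapsing = "absent"),
    neuro = neuro_panel(cerebral_hypoperfusion = "absent",
                        depression = "absent"))
}

findings_from_row <- function(row) {
  structure(list(
    systolic_dysfunction = row$sys, diastolic_dysfunction = row$dia,
    structural_damage = row$struct, remodeling = row$rem,
    severe_ef = row$sev, biventricular = row$biv
  ), class = "hlm_cardiac_findings")
}
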