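# Stage-conditional synthetic patients.
#
# Generation is criterion-driven: values are sampled just inside (or just
# outside) the configured thresholds so that, at zero missingness, the
# classifier provably returns the target code. Demographic draws cover a
# realistic adult HF range (age 40-80 y, weight 60-100 kg, height
# 1.50-1.90 m). Serum creatinine is back-solved from a target creatinine
# clearance inside (kidney-normal) or below (kidney-malfunction) the
# sex-specific reference band; for kidney-normal bundles the creatinine is
# capped so that the clearance stays at or above its reference floor and
# the sMDRD GFR stays clear of the malfunction cutoff, which is feasible
# for every demographic combination in range.

runifd <- function(n, lo, hi) stats::runif(n, lo, hi)

# creatinine giving sMDRD GFR = g for this patient
scr_for_gfr <- function(g, age, sex, black) {
  f <- 186 * age^(-0.203)
  if (sex == "female") f <- f * 0.742
  if (black) f <- f * 1.21
  (g / f)^(-1 / 1.154)
}

sample_demographics <- function() {
  demographics(age = sample(40:80, 1),
               sex = sample(c("female", "male"), 1),
               weight = round(runifd(1, 60, 100), 1),
               height = round(runifd(1, 1.50, 1.90), 2),
               black_ethnicity = stats::runif(1) < 0.15)
}

# cardiac bundle for a target H stage
sample_cardiac <- function(h) {
  normal_diams <- function() list(dd = round(runifd(1, 46, 54), 1),
                                  sd = round(runifd(1, 27, 35), 1))
  dm <- normal_diams()
  switch(as.character(h),
    "1" = cardiac_panel(
      # EF kept >= 50 so losing the adjudicated flag under missingness can
      # only degrade toward unknown, never flip to auto-derived present
      ejection_fraction = round(runifd(1, 50, 60), 1),
      systolic_dysfunction = "absent", diastolic_dysfunction = "present",
      lv_hypertrophy = "absent", previous_mi = "none",
      lv_end_diastolic_diameter = dm$dd, lv_end_systolic_diameter = dm$sd,
      lv_remodeling = "absent", rv_dysfunction = "absent"),
    "2" = {
      structural <- sample(c("hypertrophy", "stemi", "nstemi"), 1)
      cardiac_panel(
        ejection_fraction = round(runifd(1, 36, 49), 1),
        systolic_dysfunction = "present", diastolic_dysfunction = "absent",
        lv_hypertrophy = if (structural == "hypertrophy") "present" else "absent",
        previous_mi = if (structural == "hypertrophy") "none" else structural,
        lv_end_diastolic_diameter = dm$dd, lv_end_systolic_diameter = dm$sd,
        lv_remodeling = "absent", rv_dysfunction = "absent")
    },
    "3" = cardiac_panel(
      ejection_fraction = round(runifd(1, 20, 34), 1),
      systolic_dysfunction = "present", diastolic_dysfunction = "present",
      lv_hypertrophy = sample(c("present", "absent"), 1), previous_mi = "none",
      lv_end_diastolic_diameter = round(runifd(1, 56, 70), 1),
      lv_end_systolic_diameter = round(runifd(1, 37, 50), 1),
      lv_remodeling = "present", rv_dysfunction = "absent"),
    "4" = cardiac_panel(
      ejection_fraction = round(runifd(1, 15, 30), 1),
      systolic_dysfunction = "present", diastolic_dysfunction = "present",
      lv_hypertrophy = "absent", previous_mi = sample(c("none", "stemi"), 1),
      lv_end_diastolic_diameter = round(runifd(1, 56, 70), 1),
      lv_end_systolic_diameter = round(runifd(1, 37, 50), 1),
      lv_remodeling = "present", rv_dysfunction = "present"),
    stop("unreachable H target ", h, call. = FALSE)
  )
}

# hemodynamics + signs for a target L stage
sample_pulmonary <- function(l) {
  no_signs <- function(cardiac_lung = "absent", congestion = "absent",
                       edema = "absent", pleural = "absent")
    pulmonary_signs(clinical_congestion_signs = congestion,
                    pulmonary_edema = edema, pleural_effusion = pleural,
                    cardiac_lung = cardiac_lung,
                    abnormal_valsalva = "absent",
                    orthostatic_bp_abnormal = "absent",
                    nitroglycerin_response_abnormal = "absent")
  postcap <- function() hemodynamic_panel(
    mpap_rest = round(runifd(1, 26, 45), 1),
    pawp = round(runifd(1, 16, 25), 1), source = "catheterization")
  switch(as.character(l),
    "0" = list(hemo = hemodynamic_panel(mpap_rest = round(runifd(1, 12, 24), 1),
                                        pawp = round(runifd(1, 5, 14), 1),
                                        source = "catheterization"),
               signs = no_signs()),
    "1" = list(hemo = postcap(), signs = no_signs()),
    "2" = list(hemo = postcap(),
               signs = no_signs(congestion = "present",
                                edema = sample(c("present", "absent"), 1),
                                pleural = sample(c("present", "absent"), 1))),
    "3" = list(hemo = postcap(),
               signs = no_signs(cardiac_lung = "present",
                                congestion = "present",
                                edema = sample(c("present", "absent"), 1))),
    stop("unreachable L target ", l, call. = FALSE)
  )
}

# organ bundles for a target M count
sample_renal <- function(malfunction, demo, config) {
  ref <- if (demo$sex == "female") config$clcr_normal_female
         else config$clcr_normal_male
  base <- (140 - demo$age) * demo$weight / 72
  if (demo$sex == "female") base <- base * 0.85
  if (malfunction) {
    clcr_target <- runifd(1, 0.4, 0.8) * ref[1]
    scr <- base / clcr_target
    renal_panel(serum_creatinine = round(scr, 2),
                bun = round(runifd(1, 25, 60), 1),
                cystatin_c = round(runifd(1, 1.3, 2.5), 2))
  } else {
    # kidney-normal: keep clearance at or above its reference floor and the
    # sMDRD GFR clear of the 60 cutoff; an above-range clearance cannot fire
    # (only the low side does), so only the upper creatinine bound binds
    scr_hi <- min(base / (ref[1] + 2),
                  scr_for_gfr(61, demo$age, demo$sex, demo$black_ethnicity))
    scr_lo <- 0.6 * scr_hi
    renal_panel(serum_creatinine = round(runifd(1, scr_lo, scr_hi), 3),
                bun = round(runifd(1, 8, 20), 1),
                cystatin_c = round(runifd(1, 0.6, 0.95), 2))
  }
}

sample_hepatic <- function(malfunction, config) {
  on_ac <- stats::runif(1) < 1 / 3  # about a third of HF patients anticoagulated
  labs <- c("total_bilirubin_elevated", "alt_elevated", "ast_elevated",
            "alp_elevated", "ggt_elevated", "albumin_decreased", "inr_abnormal")
  args <- stats::setNames(as.list(rep("absent", length(labs))), labs)
  args$on_anticoagulants <- on_ac
  args$ascites <- "absent"; args$portal_flow_reduced <- "absent"
  args$ivc_noncollapsing <- "absent"
  if (malfunction) {
    eligible <- if (on_ac) setdiff(labs, "inr_abnormal") else labs
    k <- sample(config$liver_min_abnormal_labs:min(4, length(eligible)), 1)
    args[sample(eligible, k)] <- "present"
    if (stats::runif(1) < 0.3) args$ascites <- "present"
  }
  do.call(hepatic_panel, args)
}

sample_neuro <- function(malfunction) {
  if (malfunction) {
    which <- sample(c("hypo", "dep", "both"), 1)
    neuro_panel(cerebral_hypoperfusion = if (which != "dep") "present" else "absent",
                depression = if (which != "hypo") "present" else "absent")
  } else neuro_panel(cerebral_hypoperfusion = "absent", depression = "absent")
}

# fields eligible for missingness degradation (demographics and the
# anticoagulation flag stay; they are structural, not clinical findings)
degradable <- list(
  cardiac = c("ejection_fraction", "systolic_dysfunction",
              "diastolic_dysfunction", "lv_hypertrophy", "previous_mi",
              "lv_end_diastolic_diameter", "lv_end_systolic_diameter",
              "lv_remodeling", "rv_dysfunction"),
  hemodynamics = c("mpap_rest", "mpap_exercise", "pawp"),
  pulmonary = c("clinical_congestion_signs", "pulmonary_edema",
                "pleural_effusion", "cardiac_lung", "abnormal_valsalva",
                "orthostatic_bp_abnormal", "nitroglycerin_response_abnormal"),
  renal = c("serum_creatinine", "bun", "cystatin_c", "measured_clcr"),
  hepatic = c("total_bilirubin_elevated", "alt_elevated", "ast_elevated",
              "alp_elevated", "ggt_elevated", "albumin_decreased",
              "inr_abnormal", "ascites", "portal_flow_reduced",
              "ivc_noncollapsing"),
  neuro = c("cerebral_hypoperfusion", "depression")
)

apply_missingness <- function(record, p) {
  if (p <= 0) return(record)
  for (panel in names(degradable)) {
    for (f in degradable[[panel]]) {
      if (stats::runif(1) < p) {
        record[[panel]][[f]] <-
          if (is.numeric(record[[panel]][[f]])) NA_real_ else "unknown"
      }
    }
  }
  record
}

#' Generate one stage-conditional synthetic patient
#'
#' Builds a record that the classifier provably maps to the target
#' \code{(h, l, m)} triple when \code{missingness = 0}: cardiac flags and
#' EF chosen to satisfy exactly the target H rung, hemodynamics sampled
#' threshold-adjacent (e.g. an L >= 1 target draws mPAP in (25, 45] with
#' PAWP in (15, 25], i.e. postcapillary), and \code{m} organ-criterion
#' bundles drawn for a random subset of \{kidney, liver, brain\} of the
#' target size. With positive missingness each clinical field is
#' independently blanked to unknown, which can only degrade stages
#' (downward or to not-stageable), never raise them.
#'
#' @param target integer vector \code{c(h, l, m)}: h in 1--4, l in 0--3,
#'   m in 0--3.
#' @param seed integer seed; the draw is reproducible given
#'   \code{(target, seed)}.
#' @param missingness per-field missingness probability in [0, 1).
#' @param config an \code{\link{hlm_config}}.
#' @param patient_id optional identifier.
#' @return an \code{\link{hlm_record}}.
#' @examples
#' rec <- generate_patient(c(1, 1, 0), seed = 7)
#' classify(rec)$code  # "H1L1M0"
#' @export
generate_patient <- function(target, seed = 1L, missingness = 0,
                             config = hlm_config(),
                             patient_id = NULL) {
  stopifnot(length(target) == 3L, target[1] %in% 1:4, target[2] %in% 0:3,
            target[3] %in% 0:3, missingness >= 0, missingness < 1)
  set.seed(as.integer(seed) %% .Machine$integer.max)
  demo <- sample_demographics()
  pulm <- sample_pulmonary(target[2])
  organs <- c("kidney", "liver", "brain")
  bad <- if (target[3] > 0) sample(organs, target[3]) else character()
  rec <- hlm_record(
    patient_id = patient_id %||% sprintf("SYN-%d%d%d-%06d", target[1],
                                         target[2], target[3],
                                         as.integer(seed) %% 1000000L),
    demographics = demo,
    cardiac = sample_cardiac(target[1]),
    hemodynamics = pulm$hemo,
    pulmonary = pulm$signs,
    renal = sample_renal("kidney" %in% bad, demo, config),
    hepatic = sample_hepatic("liver" %in% bad, config),
    neuro = sample_neuro("brain" %in% bad)
  )
  apply_missingness(rec, missingness)
}

#' Generate a stage-conditional synthetic cohort
#'
#' Assigns target codes by stratified allocation -- each target gets
#' \code{floor(n * p)} patients, remainders distributed by largest
#' fractional part -- so that at zero missingness the empirical frequency
#' of each classified code equals the requested mix exactly (not merely in
#' expectation). Per-patient randomness is drawn from a substream derived
#' deterministically from \code{(seed, index)}.
#'
#' @param n number of patients, > 0.
#' @param mix named numeric vector of proportions summing to 1; names are
#'   HLM codes such as \code{"H1L1M0"}. Default: uniform over the four
#'   canonical codes H1L1M0, H2L2M1, H3L2M2, H4L3M3.
#' @param missingness per-field missingness probability in [0, 1).
#' @param seed integer master seed.
#' @param config an \code{\link{hlm_config}}.
#' @return a list of \code{\link{hlm_record}}s of length \code{n}.
#' @examples
#' cohort <- generate_cohort(8, seed = 1)
#' table(classify_cohort(cohort)$code)
#' @export
generate_cohort <- function(n,
                            mix = c(H1L1M0 = 0.25, H2L2M1 = 0.25,
                                    H3L2M2 = 0.25, H4L3M3 = 0.25),
                            missingness = 0, seed = 1L,
                            config = hlm_config()) {
  if (!is.numeric(n) || n <= 0 || n != round(n))
    stop("n must be a positive integer", call. = FALSE)
  if (is.null(names(mix)) || abs(sum(mix) - 1) > 1e-8 || any(mix < 0))
    stop("mix must be a named vector of proportions summing to 1", call. = FALSE)
  targets <- lapply(names(mix), function(code) {
    p <- parse_hlm_code(code)
    c(p$h, p$l, p$m)
  })
  # stratified allocation: floor + largest remainder
  exact <- n * mix
  counts <- floor(exact)
  rem <- n - sum(counts)
  if (rem > 0) {
    extra <- order(exact - counts, decreasing = TRUE)[seq_len(rem)]
    counts[extra] <- counts[extra] + 1
  }
  idx <- 0L
  out <- vector("list", n)
  for (t in seq_along(targets)) {
    for (k in seq_len(counts[t])) {
      idx <- idx + 1L
      sub_seed <- (as.integer(seed) * 10007L + idx) %% 2147483647L
      out[[idx]] <- generate_patient(targets[[t]], seed = sub_seed,
                                     missingness = missingness,
                                     config = config,
                                     patient_id = sprintf("SYN-%05d", idx))
    }
  }
  out
}
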