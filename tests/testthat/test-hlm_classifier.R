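test_that("the canonical mild and end-stage patterns classify to their codes", {
  # diastolic dysfunction only; postcapillary PH without signs; organs normal
  rec <- complete_normal_record("mild")
  rec$cardiac$diastolic_dysfunction <- "present"
  rec$hemodynamics <- hemodynamic_panel(mpap_rest = 30, pawp = 20,
                                        source = "catheterization")
  res <- classify(rec)
  expect_identical(res$code, "H1L1M0")

  # biventricular dysfunction + cardiac lung + kidney, liver, brain damage
  rec <- complete_normal_record("endstage")
  rec$cardiac <- cardiac_panel(
    ejection_fraction = 20, systolic_dysfunction = "present",
    diastolic_dysfunction = "present", lv_hypertrophy = "present",
    previous_mi = "stemi", lv_remodeling = "present",
    rv_dysfunction = "present")
  rec$hemodynamics <- hemodynamic_panel(mpap_rest = 45, pawp = 25)
  rec$pulmonary <- pulmonary_signs(clinical_congestion_signs = "present",
                                   pulmonary_edema = "present",
                                   cardiac_lung = "present")
  rec$renal <- renal_panel(serum_creatinine = 3.0, cystatin_c = 2.0, bun = 60)
  rec$hepatic <- hepatic_panel(total_bilirubin_elevated = "present",
                               albumin_decreased = "present",
                               ascites = "present")
  rec$neuro <- neuro_panel(depression = "present")
  res <- classify(rec)
  expect_identical(res$code, "H4L3M3")
  expect_setequal(res$malfunctioning_organs, c("kidney", "liver", "brain"))
})

test_that("empty panels give not-stageable H, L0, M0, completeness 0 and a warning note", {
  rec <- hlm_record("empty", demographics(60, "male", 80, 1.75))
  res <- classify(rec)
  expect_true(is.na(res$h_stage))
  expect_identical(res$l_stage, 0L)
  expect_identical(res$m_stage, 0L)
  expect_identical(res$code, "H?L0M0")
  expect_identical(res$completeness, 0)
  expect_match(paste(res$notes, collapse = " "), "vacuous")
})

test_that("classification refuses invalid records, listing every violation", {
  rec <- complete_normal_record("bad")
  rec$cardiac$ejection_fraction <- 150
  rec$hemodynamics$pawp <- -3
  err <- tryCatch(classify(rec), error = function(e) conditionMessage(e))
  expect_match(err, "ejection_fraction")
  expect_match(err, "pawp")
})

test_that("provenance lists every criterion exactly once and matches the stages", {
  res <- classify(complete_normal_record())
  expect_identical(anyDuplicated(res$provenance$criterion), 0L)
  expect_setequal(
    res$provenance$criterion,
    c("h.systolic_dysfunction", "h.diastolic_dysfunction",
      "h.structural_damage", "h.remodeling", "h.severe_ef",
      "h.biventricular", "l.ph_type", "l.hemodynamic_congestion",
      "l.clinical_congestion", "l.cardiac_lung", "m.kidney", "m.liver",
      "m.brain"))
  # a fully normal record fires nothing
  expect_false(any(res$provenance$fired))
  expect_identical(res$code, "H?L0M0")
  # completeness is full for the fully observed record
  expect_identical(res$completeness, 1)
})

test_that("code formatting and parsing round-trip and reject malformed codes", {
  expect_identical(parse_hlm_code("H2L2M1"), list(h = 2L, l = 2L, m = 1L))
  expect_identical(parse_hlm_code("h4l3m3"), list(h = 4L, l = 3L, m = 3L))
  expect_identical(parse_hlm_code("H?L0M0")$h, NA_integer_)
  expect_error(parse_hlm_code("H5L1M0"), "position 2")
  expect_error(parse_hlm_code("H1L4M0"), "position 4")
  expect_error(parse_hlm_code("H1L1M9"), "position 6")
  expect_error(parse_hlm_code("X1L1M0"), "position 1")
  expect_error(parse_hlm_code("H1L1M00"), "position 7")
  # format(parse(x)) normalises every valid code
  for (h in c(1:4, NA)) for (l in 0:3) for (m in 0:3) {
    code <- format_hlm_code(h, l, m)
    p <- parse_hlm_code(tolower(code))
    expect_identical(format_hlm_code(p$h, p$l, p$m), code)
  }
})

test_that("classification is deterministic and side-effect free", {
  rec <- generate_patient(c(3, 2, 2), seed = 5)
  before <- rec
  r1 <- classify(rec)
  r2 <- classify(rec)
  expect_identical(r1$code, r2$code)
  expect_identical(r1$provenance, r2$provenance)
  expect_identical(rec, before)
})

test_that("worsening exactly one criterion never lowers any stage component", {
  rank_h <- function(h) if (is.na(h)) 0L else h
  worsen_field <- function(rec, panel, field) {
    cur <- rec[[panel]][[field]]
    if (identical(cur, "present")) return(NULL)
    rec[[panel]][[field]] <- "present"
    rec
  }
  tristate_fields <- list(
    cardiac = c("systolic_dysfunction", "diastolic_dysfunction",
                "lv_hypertrophy", "lv_remodeling", "rv_dysfunction"),
    pulmonary = c("clinical_congestion_signs", "pulmonary_edema",
                  "pleural_effusion", "cardiac_lung", "abnormal_valsalva",
                  "orthostatic_bp_abnormal", "nitroglycerin_response_abnormal"),
    hepatic = c("total_bilirubin_elevated", "alt_elevated", "ast_elevated",
                "alp_elevated", "ggt_elevated", "albumin_decreased",
                "inr_abnormal", "ascites", "portal_flow_reduced",
                "ivc_noncollapsing"),
    neuro = c("cerebral_hypoperfusion", "depression"))

  set.seed(41)
  targets <- expand.grid(h = 1:4, l = 0:3, m = 0:3)
  idx <- sample(nrow(targets), 12)
  for (i in idx) {
    t <- as.integer(targets[i, ])
    rec <- generate_patient(t, seed = 1000 + i)
    base <- classify(rec)
    for (panel in names(tristate_fields)) {
      for (field in tristate_fields[[panel]]) {
        worse_rec <- worsen_field(rec, panel, field)
        if (is.null(worse_rec)) next
        worse <- classify(worse_rec)
        expect_gte(rank_h(worse$h_stage), rank_h(base$h_stage))
        expect_gte(worse$l_stage, base$l_stage)
        expect_gte(worse$m_stage, base$m_stage)
      }
    }
    # worsening previous MI from none to STEMI
    if (rec$cardiac$previous_mi == "none") {
      worse_rec <- rec; worse_rec$cardiac$previous_mi <- "stemi"
      worse <- classify(worse_rec)
      expect_gte(rank_h(worse$h_stage), rank_h(base$h_stage))
    }
  }
})

test_that("stage components are independent across their input panels", {
  rec <- generate_patient(c(2, 1, 1), seed = 9)
  base <- classify(rec)
  # perturbing only renal inputs never changes H or L
  rec2 <- rec
  rec2$renal <- renal_panel(serum_creatinine = 4.5, bun = 80, cystatin_c = 3)
  res2 <- classify(rec2)
  expect_identical(res2$h_stage, base$h_stage)
  expect_identical(res2$l_stage, base$l_stage)
  # perturbing only pulmonary signs never changes H or M
  rec3 <- rec
  rec3$pulmonary$cardiac_lung <- "present"
  res3 <- classify(rec3)
  expect_identical(res3$h_stage, base$h_stage)
  expect_identical(res3$m_stage, base$m_stage)
  # perturbing only cardiac flags never changes L or M
  rec4 <- rec
  rec4$cardiac$rv_dysfunction <- "present"
  res4 <- classify(rec4)
  expect_identical(res4$l_stage, base$l_stage)
  expect_identical(res4$m_stage, base$m_stage)
})

test_that("cohort classification reports one row per patient with errors inline", {
  cohort <- generate_cohort(8, seed = 2)
  cohort[[3]]$cardiac$ejection_fraction <- 300   # invalid
  df <- classify_cohort(cohort)
  expect_identical(nrow(df), 8L)
  expect_match(df$error[3], "ejection_fraction")
  expect_true(all(df$error[-3] == ""))
  expect_true(all(grepl("^H[1-4?]L[0-3]M[0-3]$", df$code[-3])))
})
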