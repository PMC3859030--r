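demo_m <- function() demographics(60, "male", 80, 1.75)

test_that("kidney malfunction fires on low clearance, low GFR or cystatin C", {
  cfg <- hlm_config()
  # male clearance 80 is below the 95-145 reference
  d <- flag_reference_ranges(renal_panel(measured_clcr = 80), demo_m(),
                             config = cfg)
  k <- assess_kidney(d, cfg)
  expect_identical(k$malfunction, "present")
  expect_match(paste(k$evidence, collapse = " "), "below reference")

  # elevated BUN with normal clearances never fires; supportive only
  d <- flag_reference_ranges(renal_panel(measured_clcr = 100, bun = 60,
                                         serum_creatinine = 1.0),
                             demo_m(), config = cfg)
  k <- assess_kidney(d, cfg)
  expect_identical(k$malfunction, "absent")
  expect_match(paste(k$supportive, collapse = " "), "BUN")

  # elevated cystatin C fires even with a normal clearance
  d <- flag_reference_ranges(renal_panel(measured_clcr = 100, cystatin_c = 1.8),
                             demo_m(), config = cfg)
  expect_identical(assess_kidney(d, cfg)$malfunction, "present")

  # all renal inputs missing: unknown
  d <- flag_reference_ranges(renal_panel(), demo_m(), config = cfg)
  expect_identical(assess_kidney(d, cfg)$malfunction, "unknown")
})

test_that("abnormal creatinine with normal clearance does not fire", {
  cfg <- hlm_config()
  # creatinine above its reference but measured clearance well within, at an
  # age where the sMDRD GFR (63.2) also stays clear of the 60 cutoff: the
  # creatinine excursion alone must not fire
  d <- flag_reference_ranges(renal_panel(serum_creatinine = 1.4,
                                         measured_clcr = 120),
                             demographics(30, "male", 80, 1.75), config = cfg)
  expect_gte(d$gfr_smdrd, 60)
  k <- assess_kidney(d, cfg)
  expect_identical(k$malfunction, "absent")
  expect_match(paste(k$supportive, collapse = " "), "creatinine")
})

test_that("GFR below the cutoff fires through the Cockcroft-Gault-independent route", {
  cfg <- hlm_config()
  # measured clearance normal, but creatinine high enough that sMDRD < 60
  d <- flag_reference_ranges(renal_panel(serum_creatinine = 1.6,
                                         measured_clcr = 100),
                             demo_m(), config = cfg)
  expect_lt(d$gfr_smdrd, 60)
  expect_identical(assess_kidney(d, cfg)$malfunction, "present")
})

test_that("liver needs two abnormal labs or any congestion evidence", {
  cfg <- hlm_config()
  # a single abnormal lab is not enough
  h <- hepatic_panel(alp_elevated = "present", ascites = "absent",
                     portal_flow_reduced = "absent",
                     ivc_noncollapsing = "absent")
  s <- assess_liver(h, cfg)
  expect_identical(s$malfunction, "absent")
  expect_match(paste(s$supportive, collapse = " "), "below the 2-lab rule")

  # two labs fire
  h <- hepatic_panel(total_bilirubin_elevated = "present",
                     albumin_decreased = "present")
  expect_identical(assess_liver(h, cfg)$malfunction, "present")

  # ascites alone fires (hemodynamic evidence)
  h <- hepatic_panel(ascites = "present")
  expect_identical(assess_liver(h, cfg)$malfunction, "present")
  h <- hepatic_panel(portal_flow_reduced = "present")
  expect_identical(assess_liver(h, cfg)$malfunction, "present")
  h <- hepatic_panel(ivc_noncollapsing = "present")
  expect_identical(assess_liver(h, cfg)$malfunction, "present")

  # every flag unknown: status unknown
  expect_identical(assess_liver(hepatic_panel(), cfg)$malfunction, "unknown")
})

test_that("the liver lab tally matches a counting oracle over lab subsets", {
  cfg <- hlm_config()
  labs <- c("total_bilirubin_elevated", "alt_elevated", "ast_elevated",
            "alp_elevated", "ggt_elevated", "albumin_decreased",
            "inr_abnormal")
  set.seed(31)
  for (i in 1:60) {
    k <- sample(0:7, 1)
    chosen <- sample(labs, k)
    args <- stats::setNames(as.list(rep("absent", length(labs))), labs)
    args[chosen] <- "present"
    args$ascites <- "absent"; args$portal_flow_reduced <- "absent"
    args$ivc_noncollapsing <- "absent"
    s <- assess_liver(do.call(hepatic_panel, args), cfg)
    expect_identical(s$malfunction, if (k >= 2) "present" else "absent")
  }
})

test_that("INR is excluded from the tally under anticoagulation", {
  cfg <- hlm_config()
  h <- hepatic_panel(inr_abnormal = "present", alt_elevated = "present",
                     on_anticoagulants = TRUE)
  s <- assess_liver(h, cfg)   # only ALT counts: 1 < 2
  expect_identical(s$malfunction, "absent")
  expect_match(paste(s$supportive, collapse = " "), "anticoagulated")
  h <- hepatic_panel(inr_abnormal = "present", alt_elevated = "present",
                     on_anticoagulants = FALSE)
  expect_identical(assess_liver(h, cfg)$malfunction, "present")
})

test_that("brain malfunction is a tristate OR of hypoperfusion and depression", {
  expect_identical(assess_brain(neuro_panel(depression = "present"))$malfunction,
                   "present")
  expect_identical(assess_brain(neuro_panel(cerebral_hypoperfusion = "present",
                                            depression = "absent"))$malfunction,
                   "present")
  expect_identical(assess_brain(neuro_panel(cerebral_hypoperfusion = "absent",
                                            depression = "absent"))$malfunction,
                   "absent")
  # one unknown with the other absent: no positive evidence, not unknown
  expect_identical(assess_brain(neuro_panel(cerebral_hypoperfusion = "unknown",
                                            depression = "absent"))$malfunction,
                   "absent")
  expect_identical(assess_brain(neuro_panel())$malfunction, "unknown")
})

test_that("M stage counts organs, permutation-invariantly, capped per the >=3 rule", {
  mk <- function(organ, mal, attr = "unknown") {
    st <- assess_brain(neuro_panel(depression = if (mal == "present") "present"
                                   else if (mal == "absent") "absent" else NA),
                       attributable_to_hf = attr)
    st$organ <- organ
    st
  }
  k <- mk("kidney", "present"); l <- mk("liver", "present")
  b <- mk("brain", "present"); k0 <- mk("kidney", "absent")
  b0 <- mk("brain", "unknown")

  expect_identical(stage_m(list(k0, mk("liver", "absent"), b0)), 0L)
  expect_identical(stage_m(list(k, mk("liver", "absent"), b0)), 1L)
  expect_identical(stage_m(list(k, l)), 2L)
  expect_identical(stage_m(list(k, l, b)), 3L)
  # permutation invariance
  expect_identical(stage_m(list(b, k, l)), stage_m(list(k, l, b)))
  expect_identical(stage_m(list(l, k)), 2L)
  # duplicate organs are rejected
  expect_error(stage_m(list(k, k)), "duplicate organ")
})

test_that("attribution away from heart failure excludes an organ; unknown counts", {
  cfg <- hlm_config()
  d <- flag_reference_ranges(renal_panel(measured_clcr = 40), demo_m(),
                             config = cfg)
  k_hf <- assess_kidney(d, cfg, attributable_to_hf = "present")
  k_not <- assess_kidney(d, cfg, attributable_to_hf = "absent")
  k_unk <- assess_kidney(d, cfg, attributable_to_hf = "unknown")
  expect_identical(stage_m(list(k_hf)), 1L)
  expect_identical(stage_m(list(k_not)), 0L)
  expect_identical(stage_m(list(k_unk)), 1L)
})

test_that("counting agrees with the oracle and adding an organ never lowers M", {
  set.seed(32)
  organs <- c("kidney", "liver", "brain")
  for (i in 1:50) {
    mals <- sample(c("present", "absent", "unknown"), 3, replace = TRUE)
    attrs <- sample(c("present", "absent", "unknown"), 3, replace = TRUE)
    sts <- lapply(1:3, function(j) {
      st <- assess_brain(neuro_panel(
        depression = switch(mals[j], present = "present", absent = "absent", NA)),
        attributable_to_hf = attrs[j])
      st$organ <- organs[j]
      st
    })
    m <- stage_m(sts)
    expect_identical(m, oracle_stage_m(sts))
    # flip one non-counted organ to counted: M must not drop
    for (j in 1:3) {
      if (sts[[j]]$malfunction == "present") next
      sts2 <- sts
      sts2[[j]]$malfunction <- "present"
      sts2[[j]]$evidence <- "forced"
      sts2[[j]]$attributable_to_hf <- "unknown"
      expect_gte(stage_m(sts2), m)
    }
  }
})
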