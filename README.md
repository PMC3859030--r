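# hlmstage

A deterministic, auditable rule engine for TNM-like staging of heart
failure (HF). Clinical HF classifications built on symptoms alone (NYHA,
ACC/AHA stages A–D) summarise the syndrome but not the systemic disease.
`hlmstage` implements a three-axis staging code, by analogy with the
oncological TNM system:

* **H (Heart, H1–H4)** — extent of cardiac damage, from isolated systolic
  *or* diastolic left-ventricular dysfunction (H1), through dysfunction
  with structural damage — hypertrophy or previous myocardial infarction —
  (H2), combined dysfunction and/or severe ejection fraction (EF < 35%)
  with ventricular remodeling (H3), up to biventricular dysfunction (H4).
* **L (Lung, L0–L3)** — pulmonary involvement: hemodynamic congestion
  (L1; postcapillary pulmonary hypertension, defined as mPAP > 25 mmHg
  with PAWP > 15 mmHg, or bedside surrogates of elevated filling
  pressures), clinical congestion (L2; signs and symptoms, pulmonary
  edema, pleural effusion), cardiac lung (L3; arterialization of the
  pulmonary vasculature). L0 (no involvement) is a package extension —
  the published ladder starts at L1.
* **M (Malfunction of other organs, M0–M3)** — the number of
  extra-cardiac organs (kidney, liver, brain) with HF-attributable
  malfunction, mapped 0 / 1 / 2 / ≥3 → M0 / M1 / M2 / M3.

The combined code reads like `H1L1M0` (initial-stage disease) up to
`H4L3M3` (true end-stage disease).

The M axis depends on derived renal quantities, which the package also
computes:

* Cockcroft-Gault creatinine clearance
  `ClCr = (140 − age) · weight / (72 · Scr)` (× 0.85 in women), with
  reference intervals 57–115 mL/min (women) and 95–145 mL/min (men);
* simplified-MDRD GFR
  `186 · Scr^−1.154 · age^−0.203 · 0.742^[female] · 1.21^[black]`
  (mL/min/1.73 m², Scr in mg/dL);
* body-mass index `weight / height²`.

Every clinical flag is tristate (`present` / `absent` / `unknown`), and
the engines are conservative: an unknown criterion never fires a rule, so
incomplete data can only lower a stage, never raise it. Each result
carries a per-criterion provenance table and a data-completeness score,
making every staging decision auditable.

## Worked example

```r
library(hlmstage)

rec <- hlm_record("pt-042",
  demographics(age = 68, sex = "female", weight = 72, height = 1.64),
  cardiac = cardiac_panel(ejection_fraction = 38,
    systolic_dysfunction = "present", diastolic_dysfunction = "absent",
    lv_hypertrophy = "absent", previous_mi = "nstemi",
    lv_remodeling = "absent", rv_dysfunction = "absent"),
  hemodynamics = hemodynamic_panel(mpap_rest = 32, pawp = 19,
                                   source = "catheterization"),
  pulmonary = pulmonary_signs(clinical_congestion_signs = "present",
    pulmonary_edema = "absent", pleural_effusion = "present",
    cardiac_lung = "absent", abnormal_valsalva = "absent",
    orthostatic_bp_abnormal = "absent",
    nitroglycerin_response_abnormal = "absent"),
  renal = renal_panel(serum_creatinine = 1.6, bun = 32, cystatin_c = 1.4),
  hepatic = hepatic_panel(total_bilirubin_elevated = "absent",
    alt_elevated = "absent", ast_elevated = "absent",
    alp_elevated = "absent", ggt_elevated = "absent",
    albumin_decreased = "absent", inr_abnormal = "absent",
    on_anticoagulants = FALSE, ascites = "absent",
    portal_flow_reduced = "absent", ivc_noncollapsing = "absent"),
  neuro = neuro_panel(cerebral_hypoperfusion = "absent",
                      depression = "absent"))

classify(rec)
#> HLM stage for pt-042: H2L2M1  (completeness 100%)
#>   malfunctioning organs: kidney
#>   fired criteria: h.systolic_dysfunction, h.structural_damage, l.ph_type,
#>     l.hemodynamic_congestion, l.clinical_congestion, m.kidney
#>   note: cardiac and renal findings coexist: consistent with a cardiorenal
#>     syndrome (descriptive note only)
#>   note: orientation: second-tier therapies with organ-protective cover
#>     (descriptive only)
```

Reading the result: the NSTEMI history makes the systolic dysfunction
H2 (dysfunction *with* structural damage); mPAP 32 / PAWP 19 mmHg is
postcapillary pulmonary hypertension, and the congestion signs plus
pleural effusion lift the lung stage to L2; serum creatinine 1.6 mg/dL
gives a Cockcroft-Gault clearance of 38.2 mL/min (below the female 57–115
reference) and an sMDRD GFR of 34.1 mL/min/1.73 m² (below 60), so the
kidney — the only malfunctioning organ — gives M1.

Batch use goes through CSV cohort tables (`read_cohort()` /
`classify_cohort()` / `write_cohort()`, schema in `cohort_dictionary()`),
or the command-line wrapper:

```sh
Rscript inst/cli/hlm.R simulate --n 100 --seed 1 -o cohort.csv
Rscript inst/cli/hlm.R stage cohort.csv -o staged.csv --report reports/
Rscript inst/cli/hlm.R explain cohort.csv --id SYN-00001
```

Every threshold (PH cutoffs, EF cutoffs, reference intervals, liver-lab
count, GFR cutoff) lives in `hlm_config()` and can be overridden
programmatically or via a YAML file.

`generate_patient()` / `generate_cohort()` produce stage-conditional
synthetic records: at zero missingness, classification provably recovers
the requested `(h, l, m)` target, which is how the engines are tested
end to end without clinical data.

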