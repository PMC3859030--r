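---
title: "HLM staging of heart failure: model, thresholds and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{HLM staging of heart failure: model, thresholds and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hlmstage)
```

## The staging model

Heart failure (HF) damages far more than the heart: elevated filling
pressures propagate backwards into the lungs, venous congestion and low
output injure the kidneys and liver, and hypoperfusion and chronic
illness affect the brain. `hlmstage` encodes this as a three-axis stage,
analogous to oncology's TNM: the tumour axis becomes **H** (the heart),
the lymph-node axis becomes **L** (the lungs, the heart's immediate
downstream station), and the metastasis axis becomes **M** (malfunction
of peripheral organs).

Each axis is a decision ladder evaluated top-down, highest satisfied
rung wins:

**H — cardiac damage**

| rung | rule |
|------|------|
| H4 | biventricular dysfunction (RV dysfunction together with LV systolic or diastolic dysfunction) |
| H3 | LV remodeling with combined systolic *and* diastolic dysfunction, and/or EF < 35% |
| H2 | systolic or diastolic dysfunction *with* structural damage (hypertrophy or previous MI) |
| H1 | systolic or diastolic dysfunction *without* structural damage |

With no dysfunction evidence at all the record is *not stageable*
(rendered `H?`): the published ladder starts at H1 and we do not invent
an H0. Two readings in this table were genuinely open and are resolved
as package design choices:

* The EF < 35% parenthetical on H3 attaches to the dysfunction clause,
  not to remodeling: remodeling is mandatory for H3, severe EF may only
  substitute for the dysfunction pair. An isolated severe EF therefore
  never exceeds H2.
* Severe EF counts as systolic-dysfunction evidence on the H1/H2 rungs.
  Without this, a record with EF < 35% but unadjudicated dysfunction
  flags would fall off the ladder entirely, which contradicts the intent
  that a severely reduced EF is itself dysfunction evidence.

**L — pulmonary involvement**

| rung | rule |
|------|------|
| L3 | cardiac lung (arterialized pulmonary vasculature; an adjudicated flag — no quantitative criterion exists) |
| L2 | clinical congestion: cardiopulmonary/systemic signs and symptoms; pulmonary edema always lands at least here; pleural effusion counts here by default |
| L1 | hemodynamic congestion: elevated filling pressures without clinical signs — postcapillary pulmonary hypertension, or abnormal bedside surrogates (Valsalva maneuver, orthostatic blood-pressure response, nitroglycerin response) |
| L0 | no evidence of pulmonary involvement (package extension; flagged as such in reports) |

Pulmonary hypertension (PH) is present when resting mPAP > 25 mmHg
(strict; 25.0 itself is normal). When only an exercise measurement
exists, > 30 mmHg substitutes; a resting value always takes precedence
over a conflicting exercise value. Among PH patients, PAWP ≤ 15 mmHg is
precapillary (boundary inclusive), > 15 postcapillary. Precapillary PH
counts as L1 evidence by default (`precapillary_counts_hemodynamic`):
the ladder is congestion-oriented, but both PH types are pulmonary
damage; sites that prefer to keep precapillary PH out of the congestion
ladder can switch it off. PH present with a missing wedge pressure has
an unknown subtype and, conservatively, contributes no L1 evidence.

**M — malfunction of other organs**

The count of malfunctioning extra-cardiac organs maps 0/1/2/≥3 to
M0/M1/M2/M3. The organ set is {kidney, liver, brain} — the organs for
which usable criteria exist:

* *Kidney*: creatinine clearance (measured if available, else
  Cockcroft-Gault) below its sex-specific reference interval
  (57–115 mL/min women, 95–145 men), or sMDRD GFR < 60 mL/min/1.73 m²,
  or elevated cystatin C. Serum creatinine alone never decides — it
  tracks muscle mass and can mask real renal failure — and an elevated
  BUN is supportive evidence only (it is confounded by catabolism).
* *Liver*: at least 2 abnormal labs (configurable) among total
  bilirubin, ALT, AST, alkaline phosphatase, γ-GT, albumin, INR — liver
  function tests are aspecific, so a single abnormal test is
  deliberately insufficient — or any hemodynamic/structural congestion
  evidence (ascites, reduced portal flow, a non-collapsing inferior vena
  cava), which fires on its own. The INR is excluded from the tally for
  anticoagulated patients (about a third of HF patients), and the flag
  is direction-agnostic (`inr_abnormal`): composite liver scores treat a
  *raised* INR as worse, while hepatic synthetic failure can also lower
  it; the package does not adjudicate the direction.
* *Brain*: cerebral hypoperfusion or depression, either of which
  qualifies.

Each organ carries an `attributable_to_hf` tristate. *Absent* excludes
the organ from the count; *unknown* (the default) counts, because the
engine cannot adjudicate etiology and excluding unknowns would
systematically understage multimorbid patients. Cachexia (low BMI) is
reported as a severity note rather than a counted organ — no published
BMI cutoff for that role exists — but `count_cachexia_as_organ` plus a
user-supplied cutoff can promote it. Coexisting cardiac and renal
findings add a descriptive cardiorenal-syndrome note; the five-type CRS
taxonomy is directional description, not a decision rule, and is not
computed.

## Missing-data semantics

Every clinical flag is tristate: `present`, `absent`, `unknown`.
*Unknown is not absent* — it survives construction, CSV round-trips and
classification, and is reported through the completeness score (observed
required fields / 30). The connectives are strong-Kleene (`tri_or`,
`tri_and`), and the single global rule is: **an unknown criterion never
satisfies a rung**. Consequences: stages are conservative lower bounds
under incomplete data; blanking fields can only move a stage down
(or to `H?`), never up — a property the tests check explicitly; and the
classifier never imputes.

Two derivations soften pure unknown-propagation where a measurement can
stand in for an unadjudicated flag, both config-exposed:

* systolic dysfunction, when the flag is unknown but an EF is present,
  is auto-derived as EF < 50% (`ef_systolic_dysfunction_cutoff`; a
  package default — the only published EF cutoff is the severe 35%);
* remodeling, when unadjudicated, is inferred from LV diameters above
  their reference bands. The reference diameters deserve a note: the
  source prints "systolic and diastolic normal values: 50 ± 5 mm and
  31 ± 5 mm, resp.", pairing 50 with *systolic* — the reverse of
  clinical convention, where the end-diastolic diameter is the larger.
  The defaults pair 50 ± 5 with end-diastolic and 31 ± 5 with
  end-systolic; both bands are config-overridable and the provenance
  note records the discrepancy.

## Derived renal measures

Cockcroft-Gault: `(140 − age) · weight / (72 · Scr)`, × 0.85 for women;
the 72 groups with Scr in the denominator (the standard reading of the
formula). Simplified MDRD:
`186 · Scr^−1.154 · age^−0.203 · 0.742^[female] · 1.21^[black]`. Both
take Scr in mg/dL: the constant 186 belongs to the mg/dL convention
(the µmol/L variant of the formula uses a different constant), so the
I/O layer converts µmol/L inputs (÷ 88.4) rather than the formula
accepting two unit systems. `smdrd_gfr()` has a diagnostics switch
(`check_range = FALSE`) that disables the adult age check for analytic
evaluation of the closed form. Values are carried at full precision;
rounding to one decimal happens only in reports.

Reference intervals are closed: a measurement exactly on a boundary is
*within* range (so serum creatinine 1.3 mg/dL is normal, and a male
clearance of 95 mL/min is normal). BUN and cystatin C have no published
reference interval here; the defaults (BUN ≤ 25 mg/dL, cystatin C ≤ 1.0
mg/L) are package choices, marked non-paper in provenance, and BUN is
supportive-only regardless.

## The synthetic cohort generator

`generate_patient(target, seed, missingness)` emulates
*stage-conditional physiology by construction*, not population realism:
each target rung draws values just inside the thresholds that define it
(threshold-adjacent sampling), so that at zero missingness
`classify(generate_patient(c(h, l, m)))` returns exactly `HhLlMm` — the
property the test suite verifies over the whole 4×4×4 target grid.
Concretely: an L ≥ 1 target draws mPAP uniformly in (25, 45] with PAWP
in (15, 25] (postcapillary); H bundles set the adjudicated dysfunction
flags and draw EF in rung-consistent bands (H1 keeps EF ≥ 50 so the
auto-derivation can never re-create a deleted flag); M bundles draw the
corresponding number of organ-criterion packages for a random organ
subset. Demographics are drawn once from a realistic adult HF range
(age 40–80, weight 60–100 kg, height 1.50–1.90 m), and the
kidney-normal creatinine is back-solved from a target clearance with an
upper cap keeping the sMDRD GFR clear of the 60 cutoff — feasible across
the whole demographic range.

What the generator does *not* emulate: correlated comorbidity,
epidemiologically realistic stage prevalence, measurement noise around
thresholds, longitudinal congestion dynamics. Passing round-trip tests
therefore demonstrates that the engines implement their rules exactly;
it does not validate the staging system against clinical outcomes.

`generate_cohort()` allocates targets by floor-plus-largest-remainder
stratification, so a requested mix is hit exactly, and derives each
patient's RNG substream deterministically from `(seed, index)` — two
runs with the same seed are byte-identical. Missingness blanks each
clinical field independently (demographics and the anticoagulation flag
are structural and stay), which the tests use to verify monotone
degradation.

## Numerical and interface choices

* All rule comparisons are exact floating-point comparisons against
  config values; no tolerances are injected. Boundary semantics are
  stated per threshold (PH strict `>`, wedge boundary `≤` to
  precapillary, EF strict `<`, reference intervals closed) and the test
  suite recovers each boundary by bisection to 1e-9.
* Ladders are evaluated strictly top-down; ties are impossible by
  construction, and the truth-table tests check totality (every tristate
  combination maps to exactly one outcome) against independent oracles.
* Cohort I/O is plain CSV (UTF-8, `.` decimal, mandatory header; empty
  cell = missing) — the lowest-friction clinical export format; the
  column dictionary is `cohort_dictionary()`. Unknown columns are
  rejected unless `lax`, duplicate patient ids always. Configuration
  files are flat YAML with exactly the `hlm_config()` keys; unknown keys
  are rejected so a typo cannot silently leave a default in force.
* Test and acceptance problem sizes: exhaustive truth tables (3^6
  cardiac, 3^7 pulmonary-sign, 3^6 organ combinations), a 10^4-point
  formula grid against a log-space oracle, the 4×4×4 stage-recovery grid
  at three seeds, and 25 random draws per formula-constant ratio —
  chosen to make the checks exhaustive where the space is finite and
  seconds-fast everywhere.

## Known limitations

* H, L and the liver/brain axes lean on adjudicated tristate flags
  (transmitral-flow-based diastolic dysfunction, cardiac lung, lab
  abnormality flags): the package stages findings, it does not derive
  them from raw measurements or imaging.
* `not_stageable` (`H?`) conflates "no dysfunction" with "insufficient
  data"; the completeness score and provenance table disambiguate, the
  code string does not.
* No prognostic weighting: the code orders damage extent, not risk.
  Composite liver scores (MELD, Child-Pugh) and the published HF risk
  scores are out of scope.
* The therapy-orientation note (traditional / second-tier /
  palliative) is descriptive text keyed to the canonical code patterns,
  not a recommendation engine.
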