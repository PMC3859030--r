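Package: hlmstage
Title: TNM-Like HLM Staging of Heart Failure
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A deterministic, auditable rule engine for TNM-like staging of
    heart failure. From a structured per-patient record it computes the Heart
    stage (H1-H4), the Lung stage (L0-L3, pulmonary-hypertension and
    congestion based), and the Malfunction-of-other-organs stage (M0-M3,
    counting kidney, liver and brain involvement), together with the derived
    renal quantities the rules depend on (Cockcroft-Gault creatinine
    clearance, simplified-MDRD glomerular filtration rate, body-mass index)
    and per-criterion provenance. Includes a stage-conditional synthetic
    cohort generator, CSV cohort input/output with explicit missing-value
    semantics, an overridable threshold configuration, and a command-line
    interface for batch staging.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
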