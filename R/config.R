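#' Reference configuration for the HLM staging engines
#'
#' Every numeric threshold and reference interval the rule engines use,
#' collected in one overridable object. Defaults are the published cutoffs:
#' pulmonary hypertension above 25 mmHg mean pulmonary arterial pressure at
#' rest (30 mmHg during exercise), pre/postcapillary split at a wedge
#' pressure of 15 mmHg, severe ejection fraction below 35%, serum creatinine
#' reference 0.7--1.3 mg/dL, creatinine clearance reference 57--115 mL/min in
#' women and 95--145 mL/min in men, left-ventricular end-diastolic diameter
#' 50 +/- 5 mm and end-systolic 31 +/- 5 mm, at least 2 abnormal liver labs
#' for hepatic malfunction, and a GFR malfunction cutoff of 60 mL/min/1.73m2.
#'
#' Thresholds without a published reference interval (blood urea nitrogen,
#' cystatin C, the 50% ejection-fraction cutoff used to auto-derive an
#' unadjudicated systolic-dysfunction flag) carry package defaults and are
#' marked \code{non-paper} in provenance reports.
#'
#' @param ... named overrides of any default listed below. Unknown names are
#'   rejected.
#' @return an object of class \code{hlm_config}: a named list of thresholds.
#' @examples
#' cfg <- hlm_config()
#' cfg$pawp_cutoff
#' hlm_config(pawp_cutoff = 18)$pawp_cutoff
#' @export
hlm_config <- function(...) {
  defaults <- list(
    mpap_rest_cutoff       = 25,    # mmHg, PH present iff mPAP >  cutoff at rest
    mpap_exercise_cutoff   = 30,    # mmHg, used only when resting mPAP missing
    pawp_cutoff            = 15,    # mmHg, <= cutoff precapillary, > postcapillary
    ef_severe_cutoff       = 35,    # %, severe iff EF <  cutoff (strict)
    ef_systolic_dysfunction_cutoff = 50, # %, auto-derive systolic flag; non-paper
    scr_normal             = c(0.7, 1.3),   # mg/dL, closed interval
    clcr_normal_female     = c(57, 115),    # mL/min
    clcr_normal_male       = c(95, 145),    # mL/min
    lvdd_normal            = c(mean = 50, tol = 5),  # mm, end-diastolic
    lvsd_normal            = c(mean = 31, tol = 5),  # mm, end-systolic
    liver_min_abnormal_labs = 2,    # count of abnormal liver labs to fire
    gfr_malfunction_cutoff = 60,    # mL/min/1.73m2
    bun_upper              = 25,    # mg/dL, supportive evidence only; non-paper
    cystatin_upper         = 1.0,   # mg/L; non-paper
    precapillary_counts_hemodynamic = TRUE, # precapillary PH as L1 evidence
    pleural_effusion_is_clinical    = TRUE, # pleural effusion as L2 evidence
    count_cachexia_as_organ = FALSE,        # cachexia as a counted M organ
    cachexia_bmi_cutoff     = NA_real_      # kg/m2, user-supplied if counted
  )
  overrides <- list(...)
  if (length(overrides)) {
    bad <- setdiff(names(overrides), names(defaults))
    if (length(bad) || is.null(names(overrides)) || any(names(overrides) == ""))
      stop("unknown config key(s): ", paste(bad, collapse = ", "), call. = FALSE)
    defaults[names(overrides)] <- overrides
  }
  cfg <- structure(defaults, class = "hlm_config")
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  ivals <- c("scr_normal", "clcr_normal_female", "clcr_normal_male")
  for (k in ivals) {
    v <- cfg[[k]]
    if (!is.numeric(v) || length(v) != 2L || v[1] > v[2])
      stop("config interval ", k, " must be numeric c(lower, upper) with lower <= upper",
           call. = FALSE)
  }
  for (k in c("lvdd_normal", "lvsd_normal")) {
    v <- cfg[[k]]
    if (!is.numeric(v) || length(v) != 2L || any(v <= 0))
      stop("config ", k, " must be positive c(mean, tol)", call. = FALSE)
  }
  cuts <- c("mpap_rest_cutoff", "mpap_exercise_cutoff", "pawp_cutoff",
            "ef_severe_cutoff", "ef_systolic_dysfunction_cutoff",
            "gfr_malfunction_cutoff", "bun_upper", "cystatin_upper")
  for (k in cuts) {
    v <- cfg[[k]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v <= 0)
      stop("config cutoff ", k, " must be a positive number", call. = FALSE)
  }
  if (cfg$liver_min_abnormal_labs < 1)
    stop("liver_min_abnormal_labs must be >= 1", call. = FALSE)
  invisible(cfg)
}

# upper bound of a mean +/- tol diameter reference
diam_upper <- function(v) unname(v[["mean"]] + v[["tol"]])
diam_interval <- function(v) unname(c(v[["mean"]] - v[["tol"]], v[["mean"]] + v[["tol"]]))

#' Read / write an HLM threshold configuration file
#'
#' The configuration file is flat YAML with exactly the keys of
#' \code{\link{hlm_config}}; unknown keys are rejected so that a typo cannot
#' silently leave a default in force. Writing then reading a configuration
#' reproduces it exactly.
#'
#' @param path file path.
#' @param config an \code{hlm_config} object.
#' @return \code{read_hlm_config} returns an \code{hlm_config};
#'   \code{write_hlm_config} returns \code{path} invisibly.
#' @export
read_hlm_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  raw <- lapply(raw, function(v) if (is.list(v)) unlist(v) else v)
  # restore names on the diameter entries (YAML maps keep them; lists did)
  for (k in c("lvdd_normal", "lvsd_normal")) {
    if (!is.null(raw[[k]]) && is.null(names(raw[[k]])) && length(raw[[k]]) == 2L)
      names(raw[[k]]) <- c("mean", "tol")
  }
  do.call(hlm_config, raw)
}

#' @rdname read_hlm_config
#' @export
write_hlm_config <- function(config, path) {
  stopifnot(inherits(config, "hlm_config"))
  out <- lapply(unclass(config), function(v) {
    if (!is.null(names(v))) as.list(v) else v
  })
  yaml::write_yaml(out, path)
  invisible(path)
}

#' @export
print.hlm_config <- function(x, ...) {
  cat("HLM staging thresholds:\n")
  for (k in names(x)) {
    v <- x[[k]]
    cat(sprintf("  %-34s %s\n", k,
                paste(if (!is.null(names(v)) && any(nzchar(names(v))))
                        paste0(names(v), "=", v) else format(v), collapse = " ")))
  }
  invisible(x)
}
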