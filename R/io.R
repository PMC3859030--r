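# Cohort table column dictionary. One row per patient, comma-separated,
# UTF-8, "." decimal separator, header mandatory. Empty cell = missing.
# Tristate columns accept present/absent/unknown, 1/0/blank, yes/no,
# TRUE/FALSE.

cohort_columns <- function() {
  list(
    patient_id = "id",
    age = "numeric", sex = "enum", black_ethnicity = "logical",
    weight_kg = "numeric", height_m = "numeric",
    ejection_fraction = "numeric",
    systolic_dysfunction = "tristate", diastolic_dysfunction = "tristate",
    lv_hypertrophy = "tristate", previous_mi = "enum",
    lv_end_diastolic_diameter = "numeric", lv_end_systolic_diameter = "numeric",
    lv_remodeling = "tristate", rv_dysfunction = "tristate",
    mpap_rest = "numeric", mpap_exercise = "numeric", pawp = "numeric",
    hemo_source = "enum",
    clinical_congestion_signs = "tristate", pulmonary_edema = "tristate",
    pleural_effusion = "tristate", cardiac_lung = "tristate",
    abnormal_valsalva = "tristate", orthostatic_bp_abnormal = "tristate",
    nitroglycerin_response_abnormal = "tristate",
    serum_creatinine = "numeric", creatinine_unit = "enum",
    bun = "numeric", cystatin_c = "numeric", measured_clcr = "numeric",
    total_bilirubin_elevated = "tristate", alt_elevated = "tristate",
    ast_elevated = "tristate", alp_elevated = "tristate",
    ggt_elevated = "tristate", albumin_decreased = "tristate",
    inr_abnormal = "tristate", on_anticoagulants = "logical",
    ascites = "tristate", portal_flow_reduced = "tristate",
    ivc_noncollapsing = "tristate",
    cerebral_hypoperfusion = "tristate", depression = "tristate",
    kidney_hf_attributable = "tristate", liver_hf_attributable = "tristate",
    brain_hf_attributable = "tristate"
  )
}

#' Cohort table column dictionary
#'
#' The published CSV schema for cohort files: one row per patient, a
#' mandatory unique \code{patient_id}, demographics, then the five clinical
#' panels. An empty cell means missing; tristate columns accept
#' \code{present}/\code{absent}/\code{unknown}, \code{1}/\code{0}/blank,
#' \code{yes}/\code{no} or \code{TRUE}/\code{FALSE}. The optional
#' \code{creatinine_unit} column (\code{mg_dl}, the default, or
#' \code{umol_l}) triggers unit conversion of \code{serum_creatinine} on
#' read. The optional \code{*_hf_attributable} tristates state whether each
#' organ's damage is attributed to heart failure.
#'
#' @return a data frame with columns \code{column} and \code{type}.
#' @export
cohort_dictionary <- function() {
  cols <- cohort_columns()
  data.frame(column = names(cols), type = unlist(cols, use.names = FALSE),
             stringsAsFactors = FALSE)
}

parse_num <- function(x) {
  if (is.na(x) || trimws(x) == "") return(NA_real_)
  v <- suppressWarnings(as.numeric(x))
  if (is.na(v)) stop("not a number: '", x, "'", call. = FALSE)
  v
}

parse_logical <- function(x, default = FALSE) {
  if (is.na(x) || trimws(x) == "") return(default)
  s <- tolower(trimws(x))
  if (s %in% c("true", "1", "yes")) return(TRUE)
  if (s %in% c("false", "0", "no")) return(FALSE)
  stop("not a logical: '", x, "'", call. = FALSE)
}

row_to_record <- function(row) {
  g <- function(col) if (col %in% names(row)) row[[col]] else NA_character_
  tg <- function(col) as_tristate(g(col))

  scr <- parse_num(g("serum_creatinine"))
  unit <- tolower(trimws(g("creatinine_unit") %||% ""))
  if (is.na(unit)) unit <- ""
  if (!is.na(scr) && unit %in% c("umol_l", "umol/l", "micromol_l"))
    scr <- umol_to_mgdl(scr)
  else if (!unit %in% c("", "mg_dl", "mg/dl"))
    stop("unknown creatinine_unit '", unit, "'", call. = FALSE)

  hlm_record(
    patient_id = g("patient_id"),
    demographics = demographics(
      age = parse_num(g("age")), sex = tolower(trimws(g("sex"))),
      weight = parse_num(g("weight_kg")), height = parse_num(g("height_m")),
      black_ethnicity = parse_logical(g("black_ethnicity"))),
    cardiac = cardiac_panel(
      ejection_fraction = parse_num(g("ejection_fraction")),
      systolic_dysfunction = tg("systolic_dysfunction"),
      diastolic_dysfunction = tg("diastolic_dysfunction"),
      lv_hypertrophy = tg("lv_hypertrophy"),
      previous_mi = g("previous_mi"),
      lv_end_diastolic_diameter = parse_num(g("lv_end_diastolic_diameter")),
      lv_end_systolic_diameter = parse_num(g("lv_end_systolic_diameter")),
      lv_remodeling = tg("lv_remodeling"),
      rv_dysfunction = tg("rv_dysfunction")),
    hemodynamics = hemodynamic_panel(
      mpap_rest = parse_num(g("mpap_rest")),
      mpap_exercise = parse_num(g("mpap_exercise")),
      pawp = parse_num(g("pawp")), source = g("hemo_source")),
    pulmonary = pulmonary_signs(
      clinical_congestion_signs = tg("clinical_congestion_signs"),
      pulmonary_edema = tg("pulmonary_edema"),
      pleural_effusion = tg("pleural_effusion"),
      cardiac_lung = tg("cardiac_lung"),
      abnormal_valsalva = tg("abnormal_valsalva"),
      orthostatic_bp_abnormal = tg("orthostatic_bp_abnormal"),
      nitroglycerin_response_abnormal = tg("nitroglycerin_response_abnormal")),
    renal = renal_panel(
      serum_creatinine = scr, bun = parse_num(g("bun")),
      cystatin_c = parse_num(g("cystatin_c")),
      measured_clcr = parse_num(g("measured_clcr"))),
    hepatic = hepatic_panel(
      total_bilirubin_elevated = tg("total_bilirubin_elevated"),
      alt_elevated = tg("alt_elevated"), ast_elevated = tg("ast_elevated"),
      alp_elevated = tg("alp_elevated"), ggt_elevated = tg("ggt_elevated"),
      albumin_decreased = tg("albumin_decreased"),
      inr_abnormal = tg("inr_abnormal"),
      on_anticoagulants = parse_logical(g("on_anticoagulants")),
      ascites = tg("ascites"),
      portal_flow_reduced = tg("portal_flow_reduced"),
      ivc_noncollapsing = tg("ivc_noncollapsing")),
    neuro = neuro_panel(
      cerebral_hypoperfusion = tg("cerebral_hypoperfusion"),
      depression = tg("depression"))
  )
}

record_attribution <- function(row) {
  g <- function(col) if (col %in% names(row)) as_tristate(row[[col]]) else "unknown"
  list(kidney = g("kidney_hf_attributable"),
       liver = g("liver_hf_attributable"),
       brain = g("brain_hf_attributable"))
}

#' Read a cohort CSV into patient records
#'
#' Reads a cohort table (see \code{\link{cohort_dictionary}}), validating
#' the header and every row. Row-level failures are collected rather than
#' failing fast; schema-level problems (missing mandatory columns, unknown
#' columns unless \code{lax}, duplicate patient ids) abort with a message
#' naming the offenders.
#'
#' @param path CSV file path.
#' @param lax tolerate unknown columns (they are ignored).
#' @return a list with elements \code{records} (list of
#'   \code{\link{hlm_record}}), \code{attribution} (per-record organ
#'   attribution tristates), and \code{errors} (data frame of row-level
#'   failures: \code{patient_id}, \code{row}, \code{message}).
#' @export
read_cohort <- function(path, lax = FALSE) {
  if (!file.exists(path)) stop("cohort file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                        fileEncoding = "UTF-8")
  dict <- names(cohort_columns())
  mandatory <- c("patient_id", "age", "sex", "weight_kg", "height_m")
  missing_cols <- setdiff(mandatory, names(df))
  if (length(missing_cols))
    stop("cohort file lacks mandatory column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  unknown_cols <- setdiff(names(df), dict)
  if (length(unknown_cols) && !lax)
    stop("unknown column(s) (use lax = TRUE to ignore): ",
         paste(unknown_cols, collapse = ", "), call. = FALSE)
  if (nrow(df) == 0L) stop("cohort file has no rows", call. = FALSE)
  dup <- unique(df$patient_id[duplicated(df$patient_id)])
  if (length(dup))
    stop("duplicate patient_id(s): ", paste(dup, collapse = ", "),
         call. = FALSE)

  records <- list(); attribution <- list()
  errors <- data.frame(patient_id = character(), row = integer(),
                       message = character(), stringsAsFactors = FALSE)
  for (i in seq_len(nrow(df))) {
    row <- as.list(df[i, , drop = FALSE])
    row <- lapply(row, as.character)
    rec <- tryCatch(row_to_record(row), error = function(e) e)
    if (inherits(rec, "error")) {
      errors <- rbind(errors, data.frame(
        patient_id = row$patient_id %||% "?", row = i,
        message = conditionMessage(rec), stringsAsFactors = FALSE))
    } else {
      records[[length(records) + 1L]] <- rec
      attribution[[length(attribution) + 1L]] <- record_attribution(row)
    }
  }
  list(records = records, attribution = attribution, errors = errors)
}

tristate_out <- function(x) x  # written as the word itself
num_out <- function(x) if (is.na(x)) "" else format(x, scientific = FALSE)

record_to_row <- function(rec, attribution = NULL) {
  d <- rec$demographics; ca <- rec$cardiac; he <- rec$hemodynamics
  pu <- rec$pulmonary; re <- rec$renal; hp <- rec$hepatic; ne <- rec$neuro
  at <- attribution %||% list(kidney = "unknown", liver = "unknown",
                              brain = "unknown")
  data.frame(
    patient_id = rec$patient_id,
    age = num_out(d$age), sex = d$sex,
    black_ethnicity = tolower(as.character(d$black_ethnicity)),
    weight_kg = num_out(d$weight), height_m = num_out(d$height),
    ejection_fraction = num_out(ca$ejection_fraction),
    systolic_dysfunction = ca$systolic_dysfunction,
    diastolic_dysfunction = ca$diastolic_dysfunction,
    lv_hypertrophy = ca$lv_hypertrophy, previous_mi = ca$previous_mi,
    lv_end_diastolic_diameter = num_out(ca$lv_end_diastolic_diameter),
    lv_end_systolic_diameter = num_out(ca$lv_end_systolic_diameter),
    lv_remodeling = ca$lv_remodeling, rv_dysfunction = ca$rv_dysfunction,
    mpap_rest = num_out(he$mpap_rest),
    mpap_exercise = num_out(he$mpap_exercise), pawp = num_out(he$pawp),
    hemo_source = he$source,
    clinical_congestion_signs = pu$clinical_congestion_signs,
    pulmonary_edema = pu$pulmonary_edema,
    pleural_effusion = pu$pleural_effusion, cardiac_lung = pu$cardiac_lung,
    abnormal_valsalva = pu$abnormal_valsalva,
    orthostatic_bp_abnormal = pu$orthostatic_bp_abnormal,
    nitroglycerin_response_abnormal = pu$nitroglycerin_response_abnormal,
    serum_creatinine = num_out(re$serum_creatinine),
    creatinine_unit = "mg_dl",
    bun = num_out(re$bun), cystatin_c = num_out(re$cystatin_c),
    measured_clcr = num_out(re$measured_clcr),
    total_bilirubin_elevated = hp$total_bilirubin_elevated,
    alt_elevated = hp$alt_elevated, ast_elevated = hp$ast_elevated,
    alp_elevated = hp$alp_elevated, ggt_elevated = hp$ggt_elevated,
    albumin_decreased = hp$albumin_decreased, inr_abnormal = hp$inr_abnormal,
    on_anticoagulants = tolower(as.character(hp$on_anticoagulants)),
    ascites = hp$ascites, portal_flow_reduced = hp$portal_flow_reduced,
    ivc_noncollapsing = hp$ivc_noncollapsing,
    cerebral_hypoperfusion = ne$cerebral_hypoperfusion,
    depression = ne$depression,
    kidney_hf_attributable = at$kidney,
    liver_hf_attributable = at$liver,
    brain_hf_attributable = at$brain,
    stringsAsFactors = FALSE
  )
}

#' Write patient records to a cohort CSV
#'
#' Inverse of \code{\link{read_cohort}}: the written file reproduces every
#' field, including the unknown/absent distinction, on re-reading.
#'
#' @param records a list of \code{\link{hlm_record}}s.
#' @param path output CSV path.
#' @param attribution optional list (parallel to \code{records}) of per-organ
#'   HF-attribution tristates.
#' @return \code{path}, invisibly.
#' @export
write_cohort <- function(records, path, attribution = NULL) {
  rows <- lapply(seq_along(records), function(i)
    record_to_row(records[[i]],
                  if (!is.null(attribution)) attribution[[i]] else NULL))
  df <- do.call(rbind, rows)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}
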