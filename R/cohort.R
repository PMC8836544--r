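# Baseline and longitudinal table schemas, validation, and delimited-text I/O.

.flag_columns <- c(
  "hormone_receptor_positive", "post_menopausal", "anthracycline_received",
  "radiotherapy", "diabetes", "hypertension", "dyslipidemia",
  "current_smoker", "ex_smoker", "coronary_artery_disease",
  "heart_failure_history", "atrial_fibrillation"
)

.baseline_required <- c(
  "patient_id", "age", "stage", "laterality", .flag_columns,
  "cumulative_anthracycline", "baseline_lvef", "baseline_modality"
)
.baseline_optional <- c("troponin", "bnp")

.lvef_required <- c("patient_id", "time", "lvef", "modality")
.lvef_optional <- c("hf_symptoms")

.stage_levels <- c("I", "II", "III")
.laterality_levels <- c("left", "right", "bilateral")
.modality_levels <- c("MUGA", "echo")

coerce_flag <- function(x) {
  if (is.logical(x)) return(x)
  s <- tolower(trimws(as.character(x)))
  out <- rep(NA, length(x))
  out[s %in% c("true", "t", "1", "yes")] <- TRUE
  out[s %in% c("false", "f", "0", "no")] <- FALSE
  out
}

fail_rows <- function(bad, msg, what = "row") {
  if (any(bad, na.rm = TRUE)) {
    rows <- which(bad)
    stop(sprintf("%s (%s %s)", msg, what,
                 paste(utils::head(rows, 10), collapse = ", ")), call. = FALSE)
  }
}

#' Validate a baseline covariate table
#'
#' Coerces column types and enforces the record invariants: age above 18
#' (study entry requires adult women), baseline LVEF in (0, 100],
#' non-negative anthracycline dose, and a zero/absent dose when no
#' anthracycline was received.
#'
#' @param df data frame following the baseline schema (see
#'   [read_cohort()] for the column list).
#' @return the coerced data frame, invisibly classed as validated.
#' @export
validate_baseline <- function(df) {
  missing_cols <- setdiff(.baseline_required, names(df))
  if (length(missing_cols) > 0)
    stop("baseline table is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  for (col in setdiff(.baseline_optional, names(df))) df[[col]] <- NA_real_
  df$patient_id <- as.character(df$patient_id)
  fail_rows(is.na(df$patient_id) | df$patient_id == "", "empty patient_id")
  fail_rows(duplicated(df$patient_id), "duplicate patient_id in baseline table")
  for (col in c("age", "cumulative_anthracycline", "baseline_lvef",
                "troponin", "bnp"))
    df[[col]] <- as.numeric(df[[col]])
  for (col in .flag_columns) df[[col]] <- coerce_flag(df[[col]])
  df$stage <- as.character(df$stage)
  df$laterality <- as.character(df$laterality)
  df$baseline_modality <- as.character(df$baseline_modality)
  fail_rows(!is.na(df$stage) & !df$stage %in% .stage_levels,
            "stage must be one of I, II, III")
  fail_rows(!is.na(df$laterality) & !df$laterality %in% .laterality_levels,
            "laterality must be one of left, right, bilateral")
  fail_rows(!is.na(df$baseline_modality) &
              !df$baseline_modality %in% .modality_levels,
            "baseline_modality must be MUGA or echo")
  fail_rows(!is.na(df$age) & df$age <= 18, "age must exceed 18 years")
  fail_rows(!is.na(df$baseline_lvef) &
              (df$baseline_lvef <= 0 | df$baseline_lvef > 100),
            "baseline_lvef must lie in (0, 100]")
  fail_rows(!is.na(df$cumulative_anthracycline) &
              df$cumulative_anthracycline < 0,
            "cumulative_anthracycline must be non-negative")
  fail_rows(!is.na(df$anthracycline_received) & !df$anthracycline_received &
              !is.na(df$cumulative_anthracycline) &
              df$cumulative_anthracycline > 0,
            "positive anthracycline dose recorded without anthracycline_received")
  df
}

#' Validate a longitudinal LVEF table
#'
#' @param df data frame with columns `patient_id`, `time` (days since the
#'   pre-therapy study), `lvef` (percent), `modality` (`MUGA`/`echo`) and an
#'   optional `hf_symptoms` flag.
#' @return coerced data frame, sorted by patient and time.
#' @export
validate_lvef <- function(df) {
  missing_cols <- setdiff(.lvef_required, names(df))
  if (length(missing_cols) > 0)
    stop("lvef table is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  if (!"hf_symptoms" %in% names(df)) df$hf_symptoms <- NA
  df$patient_id <- as.character(df$patient_id)
  df$time <- as.numeric(df$time)
  df$lvef <- as.numeric(df$lvef)
  df$modality <- as.character(df$modality)
  df$hf_symptoms <- coerce_flag(df$hf_symptoms)
  fail_rows(is.na(df$patient_id) | df$patient_id == "", "empty patient_id")
  fail_rows(is.na(df$time) | df$time < 0, "time must be >= 0 days")
  fail_rows(is.na(df$lvef) | df$lvef <= 0 | df$lvef > 100,
            "lvef must lie in (0, 100]")
  fail_rows(!is.na(df$modality) & !df$modality %in% .modality_levels,
            "modality must be MUGA or echo")
  fail_rows(duplicated(df[, c("patient_id", "time", "modality")]),
            "duplicate (patient_id, time, modality) measurement")
  df <- df[order(df$patient_id, df$time, df$modality), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Read a cohort from baseline and LVEF CSV files
#'
#' Both files are comma-separated UTF-8 with a header row; missing values are
#' empty fields. The baseline table has one row per patient with columns
#' `patient_id`, `age`, `stage` (I/II/III), `laterality`
#' (left/right/bilateral), the cardiovascular and treatment flags
#' (`hormone_receptor_positive`, `post_menopausal`, `anthracycline_received`,
#' `radiotherapy`, `diabetes`, `hypertension`, `dyslipidemia`,
#' `current_smoker`, `ex_smoker`, `coronary_artery_disease`,
#' `heart_failure_history`, `atrial_fibrillation`),
#' `cumulative_anthracycline` (mg/m2), `baseline_lvef` (percent),
#' `baseline_modality` (MUGA/echo) and optional `troponin` (ng/L) and `bnp`
#' (pg/mL). The LVEF table has one row per measurement with `patient_id`,
#' `time` (days since the pre-therapy study), `lvef` (percent), `modality`
#' and optional `hf_symptoms`.
#'
#' @param baseline_path,lvef_path paths to the two CSV files.
#' @return an object of class `ctrcd_cohort`: a list with elements
#'   `patients` (baseline data frame) and `lvef` (measurement data frame,
#'   sorted by patient and time).
#' @export
read_cohort <- function(baseline_path, lvef_path) {
  for (p in c(baseline_path, lvef_path))
    if (!file.exists(p)) stop("file not found: ", p, call. = FALSE)
  baseline <- read.csv(baseline_path, na.strings = "",
                       stringsAsFactors = FALSE)
  lvef <- read.csv(lvef_path, na.strings = "", stringsAsFactors = FALSE)
  cohort(validate_baseline(baseline), validate_lvef(lvef))
}

#' Assemble a cohort object from validated tables
#'
#' @param patients baseline data frame (validated with [validate_baseline()]).
#' @param lvef longitudinal data frame (validated with [validate_lvef()]).
#' @export
cohort <- function(patients, lvef) {
  orphans <- setdiff(unique(lvef$patient_id), patients$patient_id)
  if (length(orphans) > 0)
    stop("LVEF table has patients absent from the baseline table: ",
         paste(utils::head(orphans, 10), collapse = ", "), call. = FALSE)
  structure(list(patients = patients, lvef = lvef), class = "ctrcd_cohort")
}

#' @export
print.ctrcd_cohort <- function(x, ...) {
  cat(sprintf("<ctrcd_cohort> %d patients, %d LVEF measurements\n",
              nrow(x$patients), nrow(x$lvef)))
  invisible(x)
}

#' Write a cohort back to CSV files
#'
#' Inverse of [read_cohort()]; the writers are bit-stable given fixed input.
#'
#' @param x a `ctrcd_cohort`.
#' @param baseline_path,lvef_path destination file paths.
#' @export
write_cohort <- function(x, baseline_path, lvef_path) {
  stopifnot(inherits(x, "ctrcd_cohort"))
  cols <- c(.baseline_required, .baseline_optional)
  write.csv(x$patients[, cols], baseline_path, row.names = FALSE, na = "")
  write.csv(x$lvef[, c(.lvef_required, .lvef_optional)], lvef_path,
            row.names = FALSE, na = "")
  invisible(x)
}

#' Apply the study inclusion filter
#'
#' Retains patients with a pre-therapy (time 0) measurement and at least
#' `min_followups` later measurements; all others are logged with an
#' exclusion reason. Idempotent.
#'
#' @param x a `ctrcd_cohort`.
#' @param min_followups minimum number of post-baseline measurements
#'   (default 3, the study's entry requirement).
#' @return list with elements `cohort` (the filtered `ctrcd_cohort`) and
#'   `exclusions` (data frame of `patient_id`, `reason`).
#' @export
apply_inclusion_filter <- function(x, min_followups = 3) {
  stopifnot(inherits(x, "ctrcd_cohort"), min_followups >= 0)
  ids <- x$patients$patient_id
  has_baseline <- ids %in% x$lvef$patient_id[x$lvef$time == 0]
  fu <- x$lvef[x$lvef$time > 0, ]
  n_fu <- table(factor(fu$patient_id, levels = ids))
  enough_fu <- as.integer(n_fu[ids]) >= min_followups
  in_series <- ids %in% x$lvef$patient_id
  keep <- has_baseline & enough_fu
  reason <- rep(NA_character_, length(ids))
  reason[!in_series] <- "no LVEF series"
  reason[in_series & !has_baseline] <- "no pre-therapy (time 0) measurement"
  reason[has_baseline & !enough_fu] <- "insufficient follow-up"
  exclusions <- data.frame(patient_id = ids[!keep],
                           reason = reason[!keep],
                           stringsAsFactors = FALSE)
  kept_ids <- ids[keep]
  filtered <- cohort(
    x$patients[keep, , drop = FALSE],
    x$lvef[x$lvef$patient_id %in% kept_ids, , drop = FALSE]
  )
  rownames(filtered$patients) <- NULL
  rownames(filtered$lvef) <- NULL
  list(cohort = filtered, exclusions = exclusions)
}
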