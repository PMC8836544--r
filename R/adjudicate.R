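# Rule-based CTRCD adjudication from serial LVEF measurements under the
# CREC, ESC, and ASE definitions. Drops are absolute percentage points.

#' CTRCD definition
#'
#' The three accepted definitions of cancer-therapeutics-related cardiac
#' dysfunction, parameterised:
#'
#' * **CREC** — absolute LVEF decline of >= 10 points to < 55% without
#'   heart-failure symptoms, or >= 5 points to < 55% with symptoms.
#' * **ESC** — absolute decline of strictly > 10 points to below 50%.
#' * **ASE** — absolute decline of strictly > 10 points to below 53%.
#'
#' For every definition, when the baseline LVEF is below the lower limit of
#' normal (LLN), an event is instead a strictly > 10-point decline. The LLN
#' defaults to the definition's floor (55/50/53) and is overridable since no
#' separate numeric LLN is part of the definitions.
#'
#' @param name `"CREC"`, `"ESC"`, or `"ASE"`.
#' @param lln lower limit of normal for the below-LLN baseline rule
#'   (default: the definition's floor).
#' @return an object of class `ctrcd_definition` with fields
#'   `drop_asymptomatic`, `drop_symptomatic` (`NA` where the definition has
#'   no symptomatic branch), `floor`, `strict_drop`, `lln`.
#' @export
ctrcd_definition <- function(name = c("CREC", "ESC", "ASE"), lln = NULL) {
  name <- match.arg(toupper(name), c("CREC", "ESC", "ASE"))
  def <- switch(name,
    CREC = list(name = "CREC", drop_asymptomatic = 10, drop_symptomatic = 5,
                floor = 55, strict_drop = FALSE),
    ESC = list(name = "ESC", drop_asymptomatic = 10,
               drop_symptomatic = NA_real_, floor = 50, strict_drop = TRUE),
    ASE = list(name = "ASE", drop_asymptomatic = 10,
               drop_symptomatic = NA_real_, floor = 53, strict_drop = TRUE)
  )
  def$lln <- lln %||% def$floor
  stopifnot(def$floor > 0, def$floor < 100)
  structure(def, class = "ctrcd_definition")
}

as_definition <- function(definition) {
  if (inherits(definition, "ctrcd_definition")) definition
  else ctrcd_definition(definition)
}

#' Adjudicate CTRCD for a cohort of LVEF series
#'
#' Under the default `same_modality_only` policy each follow-up measurement
#' is compared against the earliest measurement of its own imaging modality
#' (LVEF values from MUGA and echocardiography are not interchangeable);
#' under `pooled` all follow-ups are compared against the patient's earliest
#' measurement regardless of modality. A measurement whose modality has no
#' earlier study serves as that modality's baseline and is itself never
#' compared; such late-appearing modality baselines are recorded in the
#' `skipped` attribute. Missing `hf_symptoms` is treated as "no symptoms",
#' so for symptom-free data the CREC definition reduces to its asymptomatic
#' branch.
#'
#' When the baseline is below the definition's LLN, the below-LLN branch
#' (> 10-point drop) takes precedence over the ordinary branches.
#'
#' @param lvef measurement data frame (`patient_id`, `time`, `lvef`,
#'   `modality`, optional `hf_symptoms`) or a `ctrcd_cohort`.
#' @param definition a `ctrcd_definition` or its name.
#' @param modality_policy `"same_modality_only"` (default) or `"pooled"`.
#' @return list with `calls` — one row per patient (`patient_id`,
#'   `definition`, `event`, `first_event_time`, `criterion`,
#'   `baseline_modality`, `baseline_lvef`) — and `summary` (`n`, `n_events`,
#'   `proportion`; `proportion` is `NA` for an empty cohort). The `calls`
#'   data frame carries the skip log as attribute `"skipped"`.
#' @export
adjudicate_cohort <- function(lvef, definition = "CREC",
                              modality_policy = c("same_modality_only",
                                                  "pooled")) {
  if (inherits(lvef, "ctrcd_cohort")) lvef <- lvef$lvef
  def <- as_definition(definition)
  modality_policy <- match.arg(modality_policy)
  if (nrow(lvef) == 0) {
    calls <- data.frame(patient_id = character(0), definition = character(0),
                        event = logical(0), first_event_time = numeric(0),
                        criterion = character(0),
                        baseline_modality = character(0),
                        baseline_lvef = numeric(0), stringsAsFactors = FALSE)
    attr(calls, "skipped") <- calls[, c("patient_id", "first_event_time")][0, ]
    return(list(calls = calls,
                summary = list(n = 0L, n_events = 0L, proportion = NA_real_)))
  }
  df <- lvef[order(lvef$patient_id, lvef$time, lvef$modality), , drop = FALSE]
  if (is.null(df$hf_symptoms)) df$hf_symptoms <- NA
  sym <- !is.na(df$hf_symptoms) & df$hf_symptoms

  key <- if (modality_policy == "same_modality_only")
    paste(df$patient_id, df$modality, sep = "\r") else df$patient_id
  first_idx <- which(!duplicated(key))
  base_of <- first_idx[match(key, key[first_idx])]
  is_baseline_row <- seq_len(nrow(df)) == base_of
  b <- df$lvef[base_of]
  drop <- b - df$lvef

  below_lln <- b < def$lln
  asym_drop_ok <- if (def$strict_drop) drop > def$drop_asymptomatic else
    drop >= def$drop_asymptomatic
  asym_evt <- !below_lln & asym_drop_ok & df$lvef < def$floor
  sym_evt <- if (is.na(def$drop_symptomatic)) rep(FALSE, nrow(df)) else
    !below_lln & sym & drop >= def$drop_symptomatic & df$lvef < def$floor
  lln_evt <- below_lln & drop > 10
  evt <- (asym_evt | sym_evt | lln_evt) & !is_baseline_row

  criterion_row <- rep(NA_character_, nrow(df))
  criterion_row[evt & sym_evt] <- "symptomatic_drop"
  criterion_row[evt & asym_evt] <- "asymptomatic_drop"
  criterion_row[evt & lln_evt] <- "below_lln_baseline_drop"

  pid <- df$patient_id
  ids <- unique(pid)
  # first qualifying follow-up per patient (df is time-ordered)
  first_evt_idx <- tapply(seq_len(nrow(df))[evt], factor(pid[evt], ids), min)
  first_evt_idx <- as.integer(first_evt_idx[ids])
  has_evt <- !is.na(first_evt_idx)

  # patient-level primary baseline: earliest measurement overall
  prim_idx <- which(!duplicated(pid))
  prim <- prim_idx[match(ids, pid[prim_idx])]
  base_mod <- df$modality[prim]
  base_lvef <- df$lvef[prim]
  # for events, report the triggering comparison's own baseline
  base_mod[has_evt] <- df$modality[base_of[first_evt_idx[has_evt]]]
  base_lvef[has_evt] <- b[first_evt_idx[has_evt]]

  calls <- data.frame(
    patient_id = ids,
    definition = def$name,
    event = has_evt,
    first_event_time = ifelse(has_evt, df$time[first_evt_idx], NA_real_),
    criterion = ifelse(has_evt, criterion_row[first_evt_idx], "none"),
    baseline_modality = base_mod,
    baseline_lvef = base_lvef,
    stringsAsFactors = FALSE
  )
  rownames(calls) <- NULL

  late_base <- is_baseline_row & df$time > df$time[prim_idx[match(pid, pid[prim_idx])]]
  skipped <- data.frame(
    patient_id = pid[late_base], time = df$time[late_base],
    modality = df$modality[late_base],
    reason = rep("no earlier baseline for this modality; used as modality baseline",
                 sum(late_base)),
    stringsAsFactors = FALSE
  )
  attr(calls, "skipped") <- skipped
  list(calls = calls,
       summary = list(n = length(ids), n_events = sum(has_evt),
                      proportion = if (length(ids) > 0)
                        sum(has_evt) / length(ids) else NA_real_))
}

#' Adjudicate CTRCD for a single LVEF series
#'
#' @param series measurement data frame for one patient (columns `time`,
#'   `lvef`, `modality`, optional `hf_symptoms`, optional `patient_id`).
#' @inheritParams adjudicate_cohort
#' @return a one-row calls data frame (see [adjudicate_cohort()]).
#' @export
adjudicate <- function(series, definition = "CREC",
                       modality_policy = c("same_modality_only", "pooled")) {
  if (is.null(series$patient_id)) series$patient_id <- "patient"
  if (length(unique(series$patient_id)) != 1)
    stop("adjudicate() expects a single patient's series; ",
         "use adjudicate_cohort() for many", call. = FALSE)
  res <- adjudicate_cohort(series, definition, modality_policy)
  res$calls
}

#' Write adjudication calls as TSV
#'
#' @param calls calls data frame from [adjudicate_cohort()].
#' @param path destination path.
#' @export
write_calls <- function(calls, path) {
  write.table(calls, path, sep = "\t", row.names = FALSE, quote = FALSE,
              na = "")
  invisible(calls)
}
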