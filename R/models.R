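# Declarative risk-model engine: load YAML model specs, evaluate factor
# predicates against the baseline table, and combine them by points, by a
# formula, or by the level-combination rule of the HFA-ICOS proforma.

#' Load a risk model specification
#'
#' Model specs are YAML files describing factors (covariate predicates with a
#' points value, formula term, or risk level), a combination mode
#' (`points_sum`, `formula`, `level_combination`), a category rule, and
#' optional per-category predicted risks for calibration. Three
#' configurations ship with the package: `"ezaz"` (points-based
#' heart-failure/cardiomyopathy model), `"nsabp31_crs"` (continuous cardiac
#' risk score in age and baseline LVEF), and `"hfa_icos_trastuzumab"`
#' (level-combination proforma).
#'
#' @param model name of a shipped model or path to a YAML file.
#' @return an object of class `risk_model`.
#' @export
load_risk_model <- function(model) {
  path <- if (file.exists(model)) model else
    system.file("extdata", "models", paste0(model, ".yaml"),
                package = "ctrcdval")
  if (!nzchar(path) || !file.exists(path))
    stop("unknown risk model: ", model, call. = FALSE)
  spec <- yaml::read_yaml(path)
  validate_risk_model(spec)
}

#' @rdname load_risk_model
#' @param spec a list with the fields of a model YAML file.
#' @export
validate_risk_model <- function(spec) {
  stopifnot(is.list(spec), !is.null(spec$model_id))
  if (!spec$combination %in% c("points_sum", "formula", "level_combination"))
    stop("unknown combination mode: ", spec$combination, call. = FALSE)
  if (!is.null(spec$predicted_risk)) {
    pr <- unlist(spec$predicted_risk)
    if (any(pr < 0 | pr > 1))
      stop("predicted_risk values must lie in [0, 1]", call. = FALSE)
  }
  if (spec$combination == "points_sum") {
    stopifnot(length(spec$factors) > 0, length(spec$categories) > 0)
  } else if (spec$combination == "formula") {
    stopifnot(is.character(spec$formula), length(spec$cutpoints) >= 1)
  } else {
    stopifnot(length(spec$factors) > 0)
    levs <- vapply(spec$factors, `[[`, "", "level")
    if (!all(levs %in% c("medium", "high", "very_high")))
      stop("level_combination factor levels must be medium/high/very_high",
           call. = FALSE)
  }
  structure(spec, class = "risk_model")
}

#' @export
print.risk_model <- function(x, ...) {
  cat(sprintf("<risk_model> %s (%s, %d factors)\n", x$model_id,
              x$combination, length(x$factors)), sep = "")
  invisible(x)
}

# Evaluate one factor predicate against a covariate vector. Returns a
# logical vector with NA where the covariate is missing.
eval_predicate <- function(x, op, value = NULL) {
  switch(op,
    "is_true" = ifelse(is.na(x), NA, as.logical(x)),
    ">=" = x >= value,
    ">" = x > value,
    "<=" = x <= value,
    "<" = x < value,
    "==" = x == value,
    "in" = ifelse(is.na(x), NA, x %in% value),
    "between" = x >= value[[1]] & x <= value[[2]],
    stop("unknown predicate op: ", op, call. = FALSE)
  )
}

model_category_levels <- function(model) {
  switch(model$combination,
    points_sum = vapply(model$categories, `[[`, "", "label"),
    formula = model$category_labels,
    level_combination = model$category_labels
  )
}

empty_assignment <- function(patients, model) {
  data.frame(
    patient_id = patients$patient_id,
    model_id = model$model_id,
    raw_score = NA_real_,
    category = factor(rep(NA_character_, nrow(patients)),
                      levels = model_category_levels(model), ordered = TRUE),
    predicted_risk = NA_real_,
    unscorable = FALSE,
    missing_fields = NA_character_,
    stringsAsFactors = FALSE
  )
}

#' Score a cohort with a risk model
#'
#' Applies the model's factor predicates to every row of the baseline table
#' and combines them according to the model's combination mode. Patients for
#' whom a required covariate is missing get an explicit unscorable record
#' naming the covariate(s) — never a silent zero.
#'
#' @param patients baseline data frame (one row per patient) or a
#'   `ctrcd_cohort`.
#' @param model a `risk_model` (see [load_risk_model()]) or its name.
#' @param include_biomarkers for level-combination models: whether factors
#'   marked `biomarker: true` (troponin/BNP thresholds) may fire. Absent
#'   optional biomarker values simply do not trigger their factors.
#' @return a risk-assignment data frame with columns `patient_id`,
#'   `model_id`, `raw_score`, `category` (ordered factor), `predicted_risk`
#'   (filled by [attach_predicted_risk()]), `unscorable`, `missing_fields`.
#' @export
score_cohort <- function(patients, model, include_biomarkers = FALSE) {
  if (inherits(patients, "ctrcd_cohort")) patients <- patients$patients
  if (is.character(model)) model <- load_risk_model(model)
  stopifnot(inherits(model, "risk_model"))
  switch(model$combination,
    points_sum = score_points_cohort(patients, model),
    formula = score_formula_cohort(patients, model),
    level_combination = score_levels_cohort(patients, model,
                                            include_biomarkers)
  )
}

score_points_cohort <- function(patients, model) {
  n <- nrow(patients)
  total <- numeric(n)
  miss <- vector("list", n)
  for (f in model$factors) {
    x <- patients[[f$field]]
    if (is.null(x)) stop("model factor references unknown covariate: ",
                         f$field, call. = FALSE)
    hit <- eval_predicate(x, f$op, f$value)
    na <- is.na(hit)
    if (any(na)) for (i in which(na)) miss[[i]] <- c(miss[[i]], f$field)
    total <- total + ifelse(na, 0, hit) * f$points
  }
  out <- empty_assignment(patients, model)
  out$unscorable <- vapply(miss, function(m) length(m) > 0, logical(1))
  out$missing_fields <- vapply(miss, function(m)
    if (length(m) > 0) paste(unique(m), collapse = ",") else NA_character_,
    character(1))
  out$raw_score <- ifelse(out$unscorable, NA_real_, total)
  labs <- model_category_levels(model)
  cat_chr <- rep(NA_character_, n)
  for (cat in model$categories)
    cat_chr[!out$unscorable & total >= cat$min & total <= cat$max] <- cat$label
  out$category <- factor(cat_chr, levels = labs, ordered = TRUE)
  out
}

score_formula_cohort <- function(patients, model) {
  req <- model$required_fields %||% all.vars(parse(text = model$formula))
  out <- empty_assignment(patients, model)
  missing_mat <- vapply(req, function(f) {
    x <- patients[[f]]
    if (is.null(x)) stop("model formula references unknown covariate: ", f,
                         call. = FALSE)
    is.na(x)
  }, logical(nrow(patients)))
  missing_mat <- matrix(missing_mat, nrow = nrow(patients))
  out$unscorable <- rowSums(missing_mat) > 0
  out$missing_fields <- apply(missing_mat, 1, function(m)
    if (any(m)) paste(req[m], collapse = ",") else NA_character_)
  env <- list2env(patients[req], parent = baseenv())
  raw <- eval(parse(text = model$formula), envir = env)
  out$raw_score <- ifelse(out$unscorable, NA_real_, raw)
  cuts <- unlist(model$cutpoints)
  idx <- 1L + rowSums(outer(out$raw_score, cuts, ">"))
  labs <- model_category_levels(model)
  out$category <- factor(ifelse(out$unscorable, NA_character_, labs[idx]),
                         levels = labs, ordered = TRUE)
  out
}

# Level-combination rule: any very_high factor -> very_high; else any high
# factor or >= high_medium_min medium factors -> high; else >= medium_min
# medium factors -> medium; else low.
combine_levels <- function(n_medium, n_high, n_very_high, rule) {
  mm <- rule$medium_min %||% 2
  hm <- rule$high_medium_min %||% 5
  ifelse(n_very_high >= 1, "very_high",
    ifelse(n_high >= 1 | n_medium >= hm, "high",
      ifelse(n_medium >= mm, "medium", "low")))
}

score_levels_cohort <- function(patients, model, include_biomarkers = FALSE) {
  n <- nrow(patients)
  counts <- list(medium = numeric(n), high = numeric(n),
                 very_high = numeric(n))
  triggered <- vector("list", n)
  for (f in model$factors) {
    if (isTRUE(f$biomarker) && !include_biomarkers) next
    x <- patients[[f$field]]
    if (is.null(x)) stop("model factor references unknown covariate: ",
                         f$field, call. = FALSE)
    hit <- eval_predicate(x, f$op, f$value)
    hit[is.na(hit)] <- FALSE  # absent optional covariates do not trigger
    counts[[f$level]] <- counts[[f$level]] + hit
    if (any(hit)) {
      lab <- f$label %||% f$field
      for (i in which(hit)) triggered[[i]] <- c(triggered[[i]], lab)
    }
  }
  out <- empty_assignment(patients, model)
  cat_chr <- combine_levels(counts$medium, counts$high, counts$very_high,
                            model$combination_rule %||% list())
  out$category <- factor(cat_chr, levels = model_category_levels(model),
                         ordered = TRUE)
  # ordinal encoding of the category doubles as the raw score
  out$raw_score <- as.numeric(out$category)
  out$triggered_factors <- vapply(triggered, function(t)
    if (length(t) > 0) paste(t, collapse = "; ") else "", character(1))
  out
}

#' Score a single patient (points model)
#'
#' Single-record convenience wrappers over [score_cohort()] for the three
#' combination modes.
#'
#' @param patient a one-row baseline data frame or named list of covariates.
#' @param model a `risk_model` with the matching combination mode.
#' @return a one-row risk-assignment data frame.
#' @export
score_points_model <- function(patient, model) {
  stopifnot(model$combination == "points_sum")
  score_cohort(as_patient_row(patient), model)
}

#' @rdname score_points_model
#' @export
score_nsabp_crs <- function(patient, model = load_risk_model("nsabp31_crs")) {
  stopifnot(model$combination == "formula")
  score_cohort(as_patient_row(patient), model)
}

#' @rdname score_points_model
#' @param include_biomarkers whether biomarker factors may fire.
#' @export
score_hfa_icos <- function(patient,
                           model = load_risk_model("hfa_icos_trastuzumab"),
                           include_biomarkers = FALSE) {
  stopifnot(model$combination == "level_combination")
  score_cohort(as_patient_row(patient), model, include_biomarkers)
}

as_patient_row <- function(patient) {
  if (is.data.frame(patient)) return(patient)
  as.data.frame(lapply(patient, function(v) if (is.null(v)) NA else v),
                stringsAsFactors = FALSE)
}

#' Attach per-category predicted risks to assignments
#'
#' For category-mapped models the predicted risk comes from the model's
#' `predicted_risk` table; for formula models with a configured risk
#' function (CRS anchors + spline knots) it is the fitted risk function
#' evaluated at each patient's raw score.
#'
#' @param assignments a risk-assignment data frame from [score_cohort()].
#' @param model the `risk_model` used to produce it.
#' @return the assignments with `predicted_risk` populated (unscorable rows
#'   stay `NA`).
#' @export
attach_predicted_risk <- function(assignments, model) {
  if (is.character(model)) model <- load_risk_model(model)
  if (!is.null(model$risk_function)) {
    anchors <- matrix(as.numeric(unlist(model$risk_function$anchors)),
                      ncol = 2, byrow = TRUE)
    fit <- fit_crs_risk_function(anchors[, 1], anchors[, 2],
                                 knots = unlist(model$risk_function$knots))
    assignments$predicted_risk <- predict(fit, assignments$raw_score)
    return(assignments)
  }
  if (is.null(model$predicted_risk))
    stop("model ", model$model_id, " has no predicted_risk mapping",
         call. = FALSE)
  pr <- model$predicted_risk
  cats <- as.character(assignments$category)
  unknown <- setdiff(unique(cats[!is.na(cats)]), names(pr))
  if (length(unknown) > 0)
    stop("no predicted risk configured for category: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  assignments$predicted_risk <- ifelse(is.na(cats), NA_real_,
                                       unlist(pr)[cats])
  assignments
}
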