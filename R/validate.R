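# Orchestration: score every model, adjudicate every definition, and
# assemble discrimination / calibration / association results per
# (model, definition) pair, with the sensitivity toggles used in external
# validation (older-patient subset, anthracycline-only subset, biomarkers).

#' Run the full external validation
#'
#' For each requested model x CTRCD definition: scores the cohort, drops
#' (and counts) unscorable patients, adjudicates CTRCD, and computes the
#' incidence-by-category table, the between-category association test, the
#' AUC with CI (over ordinal categories, and additionally over the raw
#' continuous score for formula models), and the calibration points.
#'
#' For formula models the default category rule re-derives tertiles of the
#' raw score from the analysed cohort (the external-validation convention
#' when the source model publishes no categories); set
#' `formula_categories = "config"` to use the cutpoints shipped in the
#' model config instead.
#'
#' @param x a `ctrcd_cohort`.
#' @param models character vector of model names or list of `risk_model`s.
#' @param definitions character vector of definition names.
#' @param modality_policy passed to [adjudicate_cohort()].
#' @param association_method passed to [association_test()].
#' @param auc_ci_method passed to [auc_with_ci()].
#' @param min_age optional sensitivity filter: keep patients of at least
#'   this age.
#' @param anthracycline_only sensitivity filter: keep only anthracycline
#'   recipients.
#' @param include_biomarkers let biomarker factors fire in
#'   level-combination models.
#' @param formula_categories `"tertiles"` (default) or `"config"`.
#' @param seed seed for any resampling CI.
#' @return object of class `validation_report`: a list of per-pair results
#'   plus metadata.
#' @export
run_validation <- function(x,
                           models = c("ezaz", "nsabp31_crs",
                                      "hfa_icos_trastuzumab"),
                           definitions = c("CREC", "ESC", "ASE"),
                           modality_policy = "same_modality_only",
                           association_method = "chi_square",
                           auc_ci_method = "delong",
                           min_age = NULL,
                           anthracycline_only = FALSE,
                           include_biomarkers = FALSE,
                           formula_categories = c("tertiles", "config"),
                           seed = 1L) {
  stopifnot(inherits(x, "ctrcd_cohort"),
            length(models) >= 1, length(definitions) >= 1)
  formula_categories <- match.arg(formula_categories)
  patients <- x$patients
  if (!is.null(min_age)) patients <- patients[patients$age >= min_age, ]
  if (anthracycline_only)
    patients <- patients[!is.na(patients$anthracycline_received) &
                           patients$anthracycline_received, ]
  sub <- cohort(patients,
                x$lvef[x$lvef$patient_id %in% patients$patient_id, ])

  model_objs <- lapply(models, function(m)
    if (inherits(m, "risk_model")) m else load_risk_model(m))
  results <- list()
  for (def_name in definitions) {
    adj <- adjudicate_cohort(sub, def_name, modality_policy)
    for (model in model_objs) {
      res <- tryCatch(
        validate_pair(sub, model, adj$calls, def_name,
                      association_method, auc_ci_method,
                      include_biomarkers, formula_categories, seed),
        error = function(e) list(model_id = model$model_id,
                                 definition = def_name,
                                 error = conditionMessage(e))
      )
      results[[paste(model$model_id, def_name, sep = ".")]] <- res
    }
  }
  structure(
    list(results = results,
         config = list(models = vapply(model_objs, `[[`, "", "model_id"),
                       definitions = definitions,
                       modality_policy = modality_policy,
                       association_method = association_method,
                       auc_ci_method = auc_ci_method,
                       min_age = min_age,
                       anthracycline_only = anthracycline_only,
                       include_biomarkers = include_biomarkers,
                       formula_categories = formula_categories,
                       seed = seed),
         n_patients = nrow(patients)),
    class = "validation_report"
  )
}

validate_pair <- function(sub, model, calls, def_name, association_method,
                          auc_ci_method, include_biomarkers,
                          formula_categories, seed) {
  assignments <- score_cohort(sub, model, include_biomarkers)
  if (model$combination == "formula" && formula_categories == "tertiles") {
    ok <- !assignments$unscorable
    strat <- stratify_by_quantiles(assignments$raw_score[ok], 3,
                                   labels = c("low", "medium", "high"))
    levs <- levels(strat$category)
    assignments$category <- factor(NA_character_, levels = levs,
                                   ordered = TRUE)
    assignments$category[ok] <- strat$category
  }
  assignments <- attach_predicted_risk(assignments, model)
  scored <- assignments[!assignments$unscorable, ]
  n_unscorable <- sum(assignments$unscorable)
  calls <- calls[calls$patient_id %in% scored$patient_id, ]
  tab <- incidence_table(scored, calls)
  tab_occ <- tab[tab$n_total > 0, ]
  assoc <- if (nrow(tab_occ) >= 2)
    association_test(tab_occ, association_method) else NULL
  ev <- calls$event[match(scored$patient_id, calls$patient_id)]
  auc_cat <- tryCatch(
    auc_with_ci(scored$category, ev, ci_method = auc_ci_method,
                seed = seed),
    error = function(e) NULL)
  auc_score <- if (model$combination == "formula")
    tryCatch(auc_with_ci(scored$raw_score, ev, ci_method = auc_ci_method,
                         seed = seed),
             error = function(e) NULL) else NULL
  calib <- calibration_points(scored, calls)
  list(model_id = model$model_id, definition = def_name,
       n_scored = nrow(scored), n_unscorable = n_unscorable,
       incidence = tab, association = assoc,
       auc_category = auc_cat, auc_score = auc_score,
       calibration = calib)
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("<validation_report> %d patients, %d model x definition pairs\n",
              x$n_patients, length(x$results)))
  for (res in x$results) {
    if (!is.null(res$error)) {
      cat(sprintf("\n== %s / %s: ERROR: %s\n", res$model_id, res$definition,
                  res$error))
      next
    }
    cat(sprintf("\n== %s / %s (n = %d scored, %d unscorable)\n",
                res$model_id, res$definition, res$n_scored,
                res$n_unscorable))
    print(res$incidence)
    if (!is.null(res$association))
      cat(sprintf("   %s p = %.3g\n", res$association$method_used,
                  res$association$p_value))
    if (!is.null(res$auc_category))
      cat(sprintf("   AUC (categories) %.2f (95%% CI %.2f-%.2f)\n",
                  res$auc_category$auc, res$auc_category$ci_low,
                  res$auc_category$ci_high))
    if (!is.null(res$auc_score))
      cat(sprintf("   AUC (raw score)  %.2f (95%% CI %.2f-%.2f)\n",
                  res$auc_score$auc, res$auc_score$ci_low,
                  res$auc_score$ci_high))
  }
  invisible(x)
}

#' Serialise a validation report to JSON
#'
#' @param report a `validation_report`.
#' @param path optional output path; when omitted the JSON string is
#'   returned.
#' @export
report_to_json <- function(report, path = NULL) {
  stopifnot(inherits(report, "validation_report"))
  payload <- report
  payload$results <- lapply(report$results, function(res) {
    if (!is.null(res$incidence))
      res$incidence <- as.data.frame(lapply(res$incidence, function(col)
        if (is.factor(col)) as.character(col) else col))
    res
  })
  class(payload) <- NULL
  json <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA,
                           null = "null", pretty = TRUE)
  if (!is.null(path)) {
    writeLines(json, path)
    invisible(json)
  } else json
}
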