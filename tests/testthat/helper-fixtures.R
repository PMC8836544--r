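# Programmatic fixture builders shared across the suite.

make_patient <- function(id = "P1", ...) {
  defaults <- list(
    patient_id = id, age = 55, stage = "II", laterality = "left",
    hormone_receptor_positive = TRUE, post_menopausal = FALSE,
    anthracycline_received = FALSE, cumulative_anthracycline = NA_real_,
    radiotherapy = TRUE, diabetes = FALSE, hypertension = FALSE,
    dyslipidemia = FALSE, current_smoker = FALSE, ex_smoker = FALSE,
    coronary_artery_disease = FALSE, heart_failure_history = FALSE,
    atrial_fibrillation = FALSE, baseline_lvef = 65,
    baseline_modality = "MUGA", troponin = NA_real_, bnp = NA_real_
  )
  mods <- list(...)
  defaults[names(mods)] <- mods
  as.data.frame(defaults, stringsAsFactors = FALSE)
}

make_patients <- function(...) {
  rows <- list(...)
  do.call(rbind, rows)
}

make_series <- function(id, lvefs, times = NULL, modality = "MUGA",
                        hf_symptoms = NA) {
  if (is.null(times)) times <- 90 * (seq_along(lvefs) - 1)
  data.frame(patient_id = id, time = times, lvef = lvefs,
             modality = rep(modality, length.out = length(lvefs)),
             hf_symptoms = rep(hf_symptoms, length.out = length(lvefs)),
             stringsAsFactors = FALSE)
}

# Random symptom-free trajectory ensemble (baselines >= lln_floor), used by
# the definition-nesting and monotonicity properties.
random_series_ensemble <- function(n, seed, baseline_min = 55,
                                   n_followups = 4) {
  set.seed(seed)
  ids <- sprintf("S%05d", seq_len(n))
  b <- runif(n, baseline_min, 75)
  idx <- rep(seq_len(n), each = n_followups + 1)
  visit <- rep(0:n_followups, times = n)
  lvef <- pmax(5, b[idx] - ifelse(visit == 0, 0,
                                  runif(n * (n_followups + 1), -5, 25)))
  data.frame(patient_id = ids[idx], time = 90 * visit, lvef = lvef,
             modality = "MUGA", hf_symptoms = NA, stringsAsFactors = FALSE)
}

# Build matched assignment/call tables realising given per-category counts.
make_counts_fixture <- function(categories, n_total, n_events) {
  ids <- sprintf("C%05d", seq_len(sum(n_total)))
  cat_vec <- rep(categories, n_total)
  ev <- unlist(mapply(function(n, e) c(rep(TRUE, e), rep(FALSE, n - e)),
                      n_total, n_events, SIMPLIFY = FALSE))
  assignments <- data.frame(
    patient_id = ids,
    category = factor(cat_vec, levels = categories, ordered = TRUE),
    predicted_risk = 0.1,
    stringsAsFactors = FALSE
  )
  calls <- data.frame(patient_id = ids, event = ev,
                      stringsAsFactors = FALSE)
  list(assignments = assignments, calls = calls)
}

# Type-7 empirical quantile, computed from first principles (sort + index),
# independent of stats::quantile.
quantile_oracle <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  x[lo] + (h - lo) * (x[min(lo + 1, n)] - x[lo])
}
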