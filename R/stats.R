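# Discrimination, calibration, and between-category inference for the
# external validation of the risk models.

#' Construct an incidence-by-category contingency summary
#'
#' @param categories ordered category labels.
#' @param n_total patients per category.
#' @param n_events CTRCD events per category.
#' @return object of class `contingency_summary`: a data frame with columns
#'   `category`, `n_total`, `n_events`, `proportion`.
#' @export
contingency_summary <- function(categories, n_total, n_events) {
  stopifnot(length(categories) == length(n_total),
            length(n_total) == length(n_events))
  if (any(n_events < 0 | n_events > n_total))
    stop("n_events must lie in [0, n_total]", call. = FALSE)
  out <- data.frame(
    category = factor(categories, levels = categories, ordered = TRUE),
    n_total = as.integer(n_total),
    n_events = as.integer(n_events),
    proportion = ifelse(n_total > 0, n_events / n_total, NA_real_),
    stringsAsFactors = FALSE
  )
  class(out) <- c("contingency_summary", "data.frame")
  out
}

#' @export
print.contingency_summary <- function(x, ...) {
  df <- as.data.frame(x)
  df$percent <- sprintf("%.1f%%", 100 * df$proportion)
  print(df[, c("category", "n_total", "n_events", "percent")],
        row.names = FALSE)
  invisible(x)
}

#' Tabulate CTRCD incidence by risk category
#'
#' Joins risk assignments with adjudication calls and counts events per
#' category. Assignments and calls must cover exactly the same patients;
#' unscorable assignments should be removed (and reported) upstream.
#'
#' @param assignments risk-assignment data frame (scorable rows only).
#' @param calls adjudication calls data frame.
#' @return a `contingency_summary` ordered by the model's categories.
#' @export
incidence_table <- function(assignments, calls) {
  only_a <- setdiff(assignments$patient_id, calls$patient_id)
  only_c <- setdiff(calls$patient_id, assignments$patient_id)
  if (length(only_a) > 0 || length(only_c) > 0)
    stop("assignments and calls cover different patients; ",
         "only in assignments: ",
         paste(utils::head(only_a, 5), collapse = ", "),
         "; only in calls: ",
         paste(utils::head(only_c, 5), collapse = ", "), call. = FALSE)
  if (any(is.na(assignments$category)))
    stop("assignments contain unscorable rows; drop them first",
         call. = FALSE)
  ev <- calls$event[match(assignments$patient_id, calls$patient_id)]
  levs <- levels(assignments$category)
  n_total <- as.integer(table(assignments$category))
  n_events <- as.integer(tapply(ev, assignments$category, sum,
                                default = 0L))
  contingency_summary(levs, n_total, n_events)
}

#' Association test across ordered risk categories
#'
#' Pearson chi-square without continuity correction (the default: it
#' reproduces the kind of between-category p-values reported for these
#' validation tables even with small expected cells), Fisher's exact test,
#' or `auto` (Fisher whenever any expected cell is below 5).
#'
#' @param table a `contingency_summary`. Categories with `n_total = 0` must
#'   be dropped upstream.
#' @param method `"chi_square"`, `"fisher"`, or `"auto"`.
#' @return list with `statistic` (`NA` for Fisher), `df`, `p_value`,
#'   `method_used`, and the `expected` cell counts.
#' @export
association_test <- function(table,
                             method = c("chi_square", "fisher", "auto")) {
  method <- match.arg(method)
  stopifnot(inherits(table, "contingency_summary"))
  if (nrow(table) < 2)
    stop("association test needs at least 2 categories", call. = FALSE)
  if (any(table$n_total == 0))
    stop("category with n_total = 0; drop it upstream", call. = FALSE)
  m <- rbind(events = table$n_events,
             non_events = table$n_total - table$n_events)
  colnames(m) <- as.character(table$category)
  expected <- outer(rowSums(m), colSums(m)) / sum(m)
  if (method == "auto")
    method <- if (any(expected < 5)) "fisher" else "chi_square"
  if (method == "chi_square") {
    ct <- suppressWarnings(chisq.test(m, correct = FALSE))
    list(statistic = unname(ct$statistic), df = unname(ct$parameter),
         p_value = unname(ct$p.value), method_used = "chi_square",
         expected = expected)
  } else {
    ft <- fisher.test(m)
    list(statistic = NA_real_, df = NA_integer_,
         p_value = unname(ft$p.value), method_used = "fisher",
         expected = expected)
  }
}

#' AUC with confidence interval
#'
#' Rank (Mann-Whitney) estimator of the area under the ROC curve,
#' `P(score_case > score_control) + 0.5 P(tie)`, so ordinal category scores
#' with heavy ties are handled. The 95% CI uses the DeLong structural-
#' components variance by default; a seeded percentile bootstrap is the
#' alternative.
#'
#' @param scores numeric scores or an ordered factor of risk categories.
#' @param outcomes logical event indicators, same length.
#' @param conf_level confidence level (default 0.95).
#' @param ci_method `"delong"` or `"bootstrap"`.
#' @param n_boot bootstrap resamples (default 2000).
#' @param seed seed for the bootstrap stream.
#' @return list with `auc`, `ci_low`, `ci_high`, `n_cases`, `n_controls`,
#'   `ci_method`.
#' @export
auc_with_ci <- function(scores, outcomes, conf_level = 0.95,
                        ci_method = c("delong", "bootstrap"),
                        n_boot = 2000, seed = 1L) {
  ci_method <- match.arg(ci_method)
  if (is.ordered(scores) || is.factor(scores)) scores <- as.integer(scores)
  stopifnot(length(scores) == length(outcomes))
  keep <- !is.na(scores) & !is.na(outcomes)
  scores <- scores[keep]; outcomes <- as.logical(outcomes[keep])
  n1 <- sum(outcomes); n0 <- sum(!outcomes)
  if (n1 == 0 || n0 == 0)
    stop("AUC needs at least one case and one control", call. = FALSE)
  est <- function(s, y) {
    x <- s[y]; z <- s[!y]
    # placement of each case among controls (and vice versa)
    v10 <- vapply(x, function(xi)
      (sum(z < xi) + 0.5 * sum(z == xi)) / length(z), numeric(1))
    v01 <- vapply(z, function(zi)
      (sum(x > zi) + 0.5 * sum(x == zi)) / length(x), numeric(1))
    list(auc = mean(v10), v10 = v10, v01 = v01)
  }
  e <- est(scores, outcomes)
  z <- qnorm(1 - (1 - conf_level) / 2)
  if (ci_method == "delong") {
    v <- var(e$v10) / n1 + var(e$v01) / n0
    lo <- max(0, e$auc - z * sqrt(v)); hi <- min(1, e$auc + z * sqrt(v))
  } else {
    boots <- with_local_seed(seed, {
      vapply(seq_len(n_boot), function(i) {
        idx1 <- sample(which(outcomes), n1, replace = TRUE)
        idx0 <- sample(which(!outcomes), n0, replace = TRUE)
        idx <- c(idx1, idx0)
        est(scores[idx], outcomes[idx])$auc
      }, numeric(1))
    })
    qs <- quantile(boots, c((1 - conf_level) / 2, 1 - (1 - conf_level) / 2))
    lo <- unname(qs[1]); hi <- unname(qs[2])
  }
  list(auc = e$auc, ci_low = min(lo, e$auc), ci_high = max(hi, e$auc),
       n_cases = n1, n_controls = n0, ci_method = ci_method)
}

#' Calibration points: predicted vs observed risk per category
#'
#' Observed risk is the empirical event proportion per category; its 95% CI
#' comes from an intercept-only logistic regression (Wald interval on the
#' logit scale, transformed back), whose fitted probability equals the
#' proportion exactly. Degenerate categories (0 or all events) fall back to
#' the exact Clopper-Pearson interval and are flagged.
#'
#' @param assignments risk-assignment data frame with `predicted_risk`
#'   populated (see [attach_predicted_risk()]); scorable rows only.
#' @param calls adjudication calls covering the same patients.
#' @param conf_level confidence level (default 0.95).
#' @return data frame with one row per non-empty category: `category`,
#'   `n`, `n_events`, `predicted_risk` (category mean), `observed_risk`,
#'   `ci_low`, `ci_high`, `ci_method`.
#' @export
calibration_points <- function(assignments, calls, conf_level = 0.95) {
  tab <- incidence_table(assignments, calls)
  pred <- tapply(assignments$predicted_risk, assignments$category, mean)
  z <- qnorm(1 - (1 - conf_level) / 2)
  rows <- lapply(seq_len(nrow(tab)), function(i) {
    n <- tab$n_total[i]; ev <- tab$n_events[i]
    if (n == 0) return(NULL)
    if (ev > 0 && ev < n) {
      y <- c(rep(1, ev), rep(0, n - ev))
      g <- glm(y ~ 1, family = binomial())
      mu <- unname(coef(g)); se <- sqrt(vcov(g)[1, 1])
      ci <- plogis(mu + c(-z, z) * se)
      meth <- "logistic_wald"
    } else {
      ci <- binom.test(ev, n, conf.level = conf_level)$conf.int
      meth <- "clopper_pearson"
    }
    data.frame(category = as.character(tab$category[i]), n = n,
               n_events = ev,
               predicted_risk = unname(pred[as.character(tab$category[i])]),
               observed_risk = ev / n, ci_low = ci[1], ci_high = ci[2],
               ci_method = meth, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' One-way analysis of variance
#'
#' Classical between/within decomposition (equal-variance F test), used to
#' compare continuous baseline variables across risk categories.
#'
#' @param values numeric response.
#' @param groups group labels, same length.
#' @return list with `f_statistic`, `df_between`, `df_within`, `p_value`.
#' @export
one_way_anova <- function(values, groups) {
  keep <- !is.na(values) & !is.na(groups)
  values <- values[keep]; groups <- factor(as.character(groups[keep]))
  if (nlevels(groups) < 2)
    stop("one-way ANOVA needs at least 2 groups", call. = FALSE)
  within_ss <- sum(tapply(values, groups, function(v)
    sum((v - mean(v))^2)))
  if (within_ss == 0)
    stop("zero within-group variance everywhere", call. = FALSE)
  ot <- oneway.test(values ~ groups, var.equal = TRUE)
  list(f_statistic = unname(ot$statistic),
       df_between = unname(ot$parameter[1]),
       df_within = unname(ot$parameter[2]),
       p_value = unname(ot$p.value))
}

#' Relative risk between two categories
#'
#' Ratio of event proportions (e.g. highest vs lowest risk category).
#'
#' @param table a `contingency_summary`.
#' @param numerator_category,denominator_category category labels.
#' @return the risk ratio (full precision; display rounds to 1 decimal).
#' @export
relative_risk <- function(table, numerator_category, denominator_category) {
  stopifnot(inherits(table, "contingency_summary"))
  get <- function(cat) {
    i <- match(cat, as.character(table$category))
    if (is.na(i)) stop("unknown category: ", cat, call. = FALSE)
    c(table$n_events[i], table$n_total[i])
  }
  num <- get(numerator_category); den <- get(denominator_category)
  if (den[1] == 0)
    stop("denominator category has zero events", call. = FALSE)
  (num[1] / num[2]) / (den[1] / den[2])
}
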