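# Direct textbook oracles for the inferential machinery.
chisq_oracle <- function(events, totals) {
  m <- rbind(events, totals - events)
  E <- outer(rowSums(m), colSums(m)) / sum(m)
  stat <- sum((m - E)^2 / E)
  list(stat = stat,
       p = pchisq(stat, (nrow(m) - 1) * (ncol(m) - 1), lower.tail = FALSE))
}

fisher2x2_oracle <- function(m) {
  # two-sided p by enumerating all tables with the observed margins and
  # summing hypergeometric probabilities no larger than the observed one
  rm1 <- sum(m[1, ]); rm2 <- sum(m[2, ]); cm1 <- sum(m[, 1])
  xs <- max(0, cm1 - rm2):min(cm1, rm1)
  probs <- dhyper(xs, rm1, rm2, cm1)
  p0 <- dhyper(m[1, 1], rm1, rm2, cm1)
  sum(probs[probs <= p0 * (1 + 1e-7)])
}

auc_pair_oracle <- function(scores, outcomes) {
  cases <- scores[outcomes]; controls <- scores[!outcomes]
  tot <- 0
  for (x in cases) for (z in controls)
    tot <- tot + (x > z) + 0.5 * (x == z)
  tot / (length(cases) * length(controls))
}

test_that("incidence table reproduces per-category proportions to 0.1%", {
  fx <- make_counts_fixture(c("low", "medium", "high", "very_high"),
                            c(193, 404, 27, 5), c(30, 109, 10, 2))
  tab <- incidence_table(fx$assignments, fx$calls)
  expect_equal(tab$n_total, c(193L, 404L, 27L, 5L))
  # published: 15.5 / 26.9 / 37.0 / 40.0 % (109/404 = 26.98%, so the middle
  # figure agrees to 0.1 percentage point rather than at its rounding)
  expect_true(all(abs(100 * tab$proportion -
                        c(15.5, 26.9, 37.0, 40.0)) <= 0.1))
})

test_that("incidence table contract: matched patients, no events edge case", {
  fx <- make_counts_fixture(c("low", "high"), c(5, 5), c(0, 0))
  expect_equal(incidence_table(fx$assignments, fx$calls)$proportion,
               c(0, 0))
  expect_error(incidence_table(fx$assignments, fx$calls[-1, ]),
               "different patients")
  one <- make_counts_fixture("all", 10, 3)
  expect_equal(incidence_table(one$assignments, one$calls)$proportion, 0.3)
})

test_that("chi-square equals the textbook statistic and null identity holds", {
  set.seed(8)
  for (i in 1:10) {
    k <- sample(2:4, 1)
    totals <- sample(20:200, k)
    events <- vapply(totals, function(n) rbinom(1, n, runif(1, 0.1, 0.4)),
                     integer(1))
    if (any(events == totals) || all(events == 0)) next
    tab <- contingency_summary(paste0("c", 1:k), totals, events)
    res <- association_test(tab, "chi_square")
    oracle <- chisq_oracle(events, totals)
    expect_equal(res$statistic, oracle$stat, tolerance = 1e-10)
    expect_equal(res$p_value, oracle$p, tolerance = 1e-10)
  }
  null_tab <- contingency_summary(c("a", "b"), c(50, 100), c(10, 20))
  res0 <- association_test(null_tab, "chi_square")
  expect_equal(res0$statistic, 0)
  expect_equal(res0$p_value, 1)
})

test_that("fisher 2x2 equals hypergeometric-tail enumeration", {
  set.seed(17)
  for (i in 1:10) {
    totals <- sample(5:30, 2)
    events <- c(sample(0:totals[1], 1), sample(0:totals[2], 1))
    tab <- contingency_summary(c("a", "b"), totals, events)
    res <- association_test(tab, "fisher")
    m <- rbind(events, totals - events)
    expect_equal(res$p_value, fisher2x2_oracle(m), tolerance = 1e-9)
  }
})

test_that("auto mode selects the exact test for sparse expected cells", {
  sparse <- contingency_summary(c("a", "b"), c(8, 9), c(1, 2))
  expect_equal(association_test(sparse, "auto")$method_used, "fisher")
  dense <- contingency_summary(c("a", "b"), c(200, 200), c(60, 80))
  expect_equal(association_test(dense, "auto")$method_used, "chi_square")
})

test_that("chi-square and fisher agree on well-filled 2x2s where it matters", {
  # the min-likelihood two-sided Fisher p can differ from the asymptotic
  # chi-square p by several hundredths at moderate/large p even with large
  # expected cells, so the sanity band is checked in the decision-relevant
  # regime (p <= 0.05)
  set.seed(23)
  checked <- 0
  for (i in 1:60) {
    n <- sample(200:400, 2)
    p <- runif(1, 0.25, 0.65)
    ev <- c(rbinom(1, n[1], p + runif(1, 0.05, 0.12)), rbinom(1, n[2], p))
    tab <- contingency_summary(c("a", "b"), n, ev)
    m <- rbind(ev, n - ev)
    E <- outer(rowSums(m), colSums(m)) / sum(m)
    if (any(E < 20)) next
    p_chi <- association_test(tab, "chi_square")$p_value
    if (p_chi > 0.05) next
    p_f <- association_test(tab, "fisher")$p_value
    expect_lt(abs(p_chi - p_f), 0.02)
    checked <- checked + 1
  }
  expect_gt(checked, 5)
})

test_that("AUC handles ties, edge cases, and matches pair counting", {
  expect_equal(auc_with_ci(rep(1, 10), c(rep(TRUE, 4), rep(FALSE, 6)))$auc,
               0.5)
  perfect <- auc_with_ci(c(5, 6, 1, 2), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(perfect$auc, 1.0)
  expect_equal(perfect$ci_high, 1.0)
  # cases {3, 2}, controls {1, 3}: 4 pairs -> 2 concordant + 1 tie / 4
  mixed <- auc_with_ci(c(3, 2, 1, 3), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(mixed$auc, 0.625)
  expect_error(auc_with_ci(1:4, rep(TRUE, 4)), "at least one")

  set.seed(13)
  for (i in 1:8) {
    n <- sample(10:50, 1)
    scores <- sample(1:6, n, replace = TRUE)  # heavy ties
    outcomes <- runif(n) < 0.4
    if (sum(outcomes) == 0 || sum(!outcomes) == 0) next
    expect_equal(auc_with_ci(scores, outcomes)$auc,
                 auc_pair_oracle(scores, outcomes), tolerance = 1e-12)
  }
})

test_that("AUC is invariant under strictly increasing score transforms", {
  set.seed(29)
  scores <- rnorm(60)
  outcomes <- runif(60) < plogis(scores)
  a1 <- auc_with_ci(scores, outcomes)$auc
  expect_equal(auc_with_ci(exp(scores), outcomes)$auc, a1)
  expect_equal(auc_with_ci(rank(scores), outcomes)$auc, a1)
})

test_that("DeLong interval agrees with the pROC reference implementation", {
  skip_if_not_installed("pROC")
  set.seed(37)
  scores <- c(rnorm(40, 1), rnorm(60))
  outcomes <- rep(c(TRUE, FALSE), c(40, 60))
  mine <- auc_with_ci(scores, outcomes)
  ref <- suppressMessages(pROC::ci.auc(outcomes, scores, method = "delong"))
  expect_equal(mine$auc, as.numeric(ref[2]), tolerance = 1e-10)
  expect_equal(mine$ci_low, as.numeric(ref[1]), tolerance = 1e-6)
  expect_equal(mine$ci_high, as.numeric(ref[3]), tolerance = 1e-6)
})

test_that("calibration: observed risk is the exact event proportion and the
           logistic MLE reproduces it", {
  fx <- make_counts_fixture("medium", 404, 109)
  cp <- calibration_points(fx$assignments, fx$calls)
  expect_equal(cp$observed_risk, 109 / 404)
  g <- glm(c(rep(1, 109), rep(0, 404 - 109)) ~ 1, family = binomial())
  expect_equal(plogis(unname(coef(g))), cp$observed_risk, tolerance = 1e-8)
  expect_equal(cp$ci_method, "logistic_wald")
  expect_true(cp$ci_low <= cp$observed_risk &
                cp$observed_risk <= cp$ci_high)
})

test_that("degenerate categories fall back to a flagged exact interval", {
  fx <- make_counts_fixture(c("a", "b"), c(20, 15), c(0, 15))
  cp <- calibration_points(fx$assignments, fx$calls)
  expect_equal(cp$observed_risk, c(0, 1))
  expect_equal(cp$ci_method, rep("clopper_pearson", 2))
  expect_true(all(cp$ci_low <= cp$observed_risk &
                    cp$observed_risk <= cp$ci_high))
})

test_that("Wald logistic CI matches a parametric-bootstrap oracle", {
  set.seed(41)
  for (case in list(c(150, 45), c(400, 110))) {
    n <- case[1]; ev <- case[2]
    fx <- make_counts_fixture("g", n, ev)
    cp <- calibration_points(fx$assignments, fx$calls)
    boot <- rbinom(10000, n, ev / n) / n
    qs <- unname(quantile(boot, c(0.025, 0.975)))
    expect_lt(abs(cp$ci_low - qs[1]), 0.02)
    expect_lt(abs(cp$ci_high - qs[2]), 0.02)
  }
})

test_that("one-way ANOVA: null identity, t-squared identity, SS oracle", {
  same <- one_way_anova(c(1, 2, 3, 1, 2, 3), rep(c("a", "b"), each = 3))
  expect_equal(same$f_statistic, 0)
  expect_equal(same$p_value, 1)

  set.seed(43)
  x <- rnorm(20); y <- rnorm(25, 0.5)
  res <- one_way_anova(c(x, y), rep(c("x", "y"), c(20, 25)))
  tt <- t.test(x, y, var.equal = TRUE)
  expect_equal(res$f_statistic, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(res$p_value, tt$p.value, tolerance = 1e-10)

  vals <- rnorm(60); grp <- sample(c("a", "b", "c"), 60, replace = TRUE)
  res3 <- one_way_anova(vals, grp)
  gm <- mean(vals)
  ssb <- sum(tapply(vals, grp, function(v) length(v) * (mean(v) - gm)^2))
  ssw <- sum(tapply(vals, grp, function(v) sum((v - mean(v))^2)))
  f_oracle <- (ssb / 2) / (ssw / (60 - 3))
  expect_equal(res3$f_statistic, f_oracle, tolerance = 1e-10)
  expect_error(one_way_anova(c(1, 1, 2, 2), c("a", "a", "b", "b")),
               "zero within-group variance")
})

test_that("relative risk reproduces the published fold-differences", {
  tabs <- validation_cohort_tables()
  expect_equal(round(relative_risk(tabs$nsabp_tertiles, "high", "low"), 1),
               1.7)
  expect_equal(round(relative_risk(tabs$hfa_icos, "high", "low"), 1), 2.4)
  flat <- contingency_summary(c("a", "b"), c(100, 50), c(20, 10))
  expect_equal(relative_risk(flat, "b", "a"), 1.0)
  zero <- contingency_summary(c("a", "b"), c(100, 50), c(0, 10))
  expect_error(relative_risk(zero, "b", "a"), "zero events")
})

test_that("run_validation applies subset filters and round-trips to JSON", {
  gen <- generate_cohort(generator_config(n_patients = 400, seed = 9))
  rep1 <- run_validation(gen$cohort, models = "nsabp31_crs",
                         definitions = "CREC", min_age = 60)
  expect_equal(rep1$n_patients, sum(gen$cohort$patients$age >= 60))
  rep2 <- run_validation(gen$cohort, models = "nsabp31_crs",
                         definitions = "CREC", anthracycline_only = TRUE)
  expect_equal(rep2$n_patients,
               sum(gen$cohort$patients$anthracycline_received))

  path <- withr::local_tempfile(fileext = ".json")
  report_to_json(rep1, path)
  parsed <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  res <- rep1$results[["nsabp31_crs.CREC"]]
  expect_equal(parsed$results$nsabp31_crs.CREC$association$p_value,
               res$association$p_value, tolerance = 1e-12)
  expect_equal(parsed$results$nsabp31_crs.CREC$incidence$n_events,
               res$incidence$n_events)
})
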