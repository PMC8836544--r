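# Restricted (natural) cubic spline fit of the CRS -> cardiac-event-risk
# relation, anchored on (score, risk) pairs read off a cumulative-incidence
# curve. Least squares on the natural-spline basis; linear beyond the
# boundary knots; evaluations clipped to [0, 1].

#' Fit a restricted cubic spline risk function
#'
#' Fits `risk ~ ns(score)` by least squares on the natural cubic spline
#' basis. The first and last knot are used as boundary knots (the fit is
#' linear beyond them); the remaining knots are interior. With knots at
#' every distinct anchor, the fit interpolates the anchors.
#'
#' @param crs numeric anchor scores.
#' @param risk anchor risks in `[0, 1]`, same length as `crs`.
#' @param knots knot locations (at least 3), within the anchor range.
#' @return an object of class `crs_risk_function` with a [predict()] method.
#' @export
fit_crs_risk_function <- function(crs, risk, knots) {
  stopifnot(length(crs) == length(risk))
  if (length(unique(crs)) < 3)
    stop("need at least 3 distinct anchor scores", call. = FALSE)
  dup <- duplicated(crs)
  if (any(dup)) {
    for (v in unique(crs[dup]))
      if (length(unique(risk[crs == v])) > 1)
        stop("conflicting risks at duplicated anchor score ", v,
             call. = FALSE)
  }
  knots <- sort(unique(knots))
  if (length(knots) < 3)
    stop("need at least 3 knots (2 boundary + 1 interior)", call. = FALSE)
  if (min(knots) < min(crs) || max(knots) > max(crs))
    stop("knots must lie within the anchor score range", call. = FALSE)
  boundary <- range(knots)
  interior <- knots[-c(1, length(knots))]
  basis <- splines::ns(crs, knots = interior, Boundary.knots = boundary)
  X <- cbind(1, basis)
  fit <- lm.fit(X, risk)
  structure(
    list(coefficients = fit$coefficients, interior = interior,
         boundary = boundary,
         anchors = data.frame(crs = crs, risk = risk)),
    class = "crs_risk_function"
  )
}

#' Evaluate a fitted CRS risk function
#'
#' @param object a `crs_risk_function`.
#' @param newdata scores at which to evaluate.
#' @param ... unused.
#' @return predicted risks, clipped to `[0, 1]`; `NA` scores give `NA`.
#' @export
predict.crs_risk_function <- function(object, newdata, ...) {
  x <- as.numeric(newdata)
  out <- rep(NA_real_, length(x))
  ok <- !is.na(x)
  if (any(ok)) {
    basis <- splines::ns(x[ok], knots = object$interior,
                         Boundary.knots = object$boundary)
    beta <- object$coefficients
    beta[is.na(beta)] <- 0
    out[ok] <- pmin(1, pmax(0, drop(cbind(1, basis) %*% beta)))
  }
  out
}

#' @export
print.crs_risk_function <- function(x, ...) {
  cat(sprintf("<crs_risk_function> %d anchors, knots at %s\n",
              nrow(x$anchors),
              paste(c(x$boundary[1], x$interior, x$boundary[2]),
                    collapse = ", ")))
  invisible(x)
}

#' Stratify scores by empirical quantiles
#'
#' Cutpoints are the `1/k, ..., (k-1)/k` empirical quantiles; a score equal
#' to a cutpoint goes to the lower group (consistent with "score <= c"
#' category labelling). Heavy ties can collapse cutpoints, in which case
#' fewer than `k` groups are returned and the result is flagged.
#'
#' @param scores numeric vector (non-empty).
#' @param k number of groups (>= 2), e.g. 3 for tertiles, 5 for quintiles.
#' @param labels optional group labels (length = number of distinct groups).
#' @return list with `category` (ordered factor), `cutpoints`, `sizes`, and
#'   `degenerate` (TRUE when ties collapsed the grouping).
#' @export
stratify_by_quantiles <- function(scores, k, labels = NULL) {
  stopifnot(k >= 2, length(scores) > 0)
  if (length(unique(scores[!is.na(scores)])) == 1) {
    lab <- labels %||% "group1"
    return(list(
      category = factor(rep(lab[1], length(scores)), levels = lab[1],
                        ordered = TRUE),
      cutpoints = numeric(0), sizes = length(scores), degenerate = TRUE
    ))
  }
  cuts <- unname(quantile(scores, probs = seq_len(k - 1) / k, na.rm = TRUE))
  degenerate <- anyDuplicated(cuts) > 0
  cuts <- unique(cuts)
  n_groups <- length(cuts) + 1
  labels <- labels %||% paste0("Q", seq_len(n_groups))
  stopifnot(length(labels) == n_groups)
  idx <- 1L + rowSums(outer(scores, cuts, ">"))
  category <- factor(labels[idx], levels = labels, ordered = TRUE)
  list(category = category, cutpoints = cuts,
       sizes = as.integer(table(category)), degenerate = degenerate)
}
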