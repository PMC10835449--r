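#' Wilson score interval for a binomial proportion
#'
#' @param s number of successes (vectorized).
#' @param n number of trials.
#' @param conf confidence level.
#' @return data.frame with columns `low`, `high`.
#' @export
wilson_ci <- function(s, n, conf = 0.95) {
  stopifnot(all(n > 0), all(s >= 0), all(s <= n))
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- s / n
  denom <- 1 + z^2 / n
  center <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  data.frame(low = center - half, high = center + half)
}

#' Aggregate variants by mutational context
#'
#' Collapses a variant table to one row per (context, alt, methylation bin)
#' key, with variant and singleton counts and the observed proportion of
#' singletons. This is the observation unit of the calibration fit, weighted
#' by the number of observations per context.
#'
#' @param variants variant data.frame carrying `context_key`, `mu` and
#'   `is_singleton` (see [assign_context()]).
#' @param mut_table optional mutability table; if supplied and the context
#'   columns are absent they are attached first.
#' @return data.frame with columns `context_key`, `mu`, `context_class`,
#'   `n`, `s`, `ps`, sorted by `mu`.
#' @export
aggregate_contexts <- function(variants, mut_table = NULL) {
  if (!is.null(mut_table) && !("context_key" %in% names(variants)))
    variants <- assign_context(variants, mut_table)
  if (nrow(variants) == 0) stop("no variants to aggregate")
  stopifnot(all(c("context_key", "mu", "is_singleton") %in% names(variants)))
  n <- tapply(variants$is_singleton, variants$context_key, length)
  s <- tapply(variants$is_singleton, variants$context_key, sum)
  mu <- tapply(variants$mu, variants$context_key, function(x) x[1])
  cls <- tapply(variants$context_class, variants$context_key,
                function(x) x[1])
  out <- data.frame(
    context_key = names(n), mu = as.numeric(mu),
    context_class = as.character(cls),
    n = as.integer(n), s = as.integer(s),
    ps = as.numeric(s) / as.numeric(n),
    stringsAsFactors = FALSE
  )
  out <- out[order(out$mu, out$context_key), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Calibrate the proportion-of-singletons model on a neutral variant class
#'
#' Fits the weighted least-squares model `ps_c ~ alpha + beta * t(mu_c)` over
#' context aggregates, with weights equal to the variant count per context.
#' With `transform = "identity"` this is the MAPS calibration; with
#' `transform = "sqrt"` the regressor is the square root of mutability, the
#' TRAPS recalibration that removes the bias against low-mutability
#' (transversion) contexts caused by saturation and mutational recurrence.
#'
#' @param aggregates context aggregates from [aggregate_contexts()], computed
#'   on the neutral (calibration) variant class.
#' @param transform `"sqrt"` (TRAPS, default) or `"identity"` (MAPS).
#' @return An object of class `calibration_model`: list with `transform`,
#'   `intercept`, `slope`, and the calibration `aggregates` augmented with
#'   `fitted` and `residual` columns.
#' @export
fit_calibration <- function(aggregates, transform = c("sqrt", "identity")) {
  transform <- match.arg(transform)
  if (any(aggregates$mu <= 0)) stop("mutability values must be positive")
  t_mu <- transform_mu(aggregates$mu, transform)
  if (length(unique(t_mu)) < 2)
    stop("calibration needs at least 2 distinct mutability values")
  fit <- stats::lm(ps ~ t_mu, data = cbind(aggregates, t_mu = t_mu),
                   weights = aggregates$n)
  co <- stats::coef(fit)
  aggregates$fitted <- as.numeric(stats::fitted(fit))
  aggregates$residual <- aggregates$ps - aggregates$fitted
  structure(
    list(transform = transform,
         intercept = unname(co[1]), slope = unname(co[2]),
         aggregates = aggregates),
    class = "calibration_model"
  )
}

transform_mu <- function(mu, transform) {
  switch(transform, identity = mu, sqrt = sqrt(mu),
         stop("unknown transform: ", transform))
}

#' Predicted proportion of singletons under a calibration model
#'
#' @param model a `calibration_model`.
#' @param mu vector of mutability values.
#' @return predicted proportions, clamped to \[0, 1\]; the number of clamped
#'   predictions is reported via the `"clamped"` attribute.
#' @export
predict_ps <- function(model, mu) {
  raw <- model$intercept + model$slope * transform_mu(mu, model$transform)
  p <- pmin(pmax(raw, 0), 1)
  attr(p, "clamped") <- sum(raw < 0 | raw > 1)
  p
}

#' @export
print.calibration_model <- function(x, ...) {
  cat(sprintf(
    "<calibration_model> transform=%s  ps ~ %.4f + %.4f * t(mu)  (%d contexts, %d variants)\n",
    x$transform, x$intercept, x$slope, nrow(x$aggregates),
    sum(x$aggregates$n)))
  invisible(x)
}

#' Selection score (MAPS/TRAPS) of a variant subset
#'
#' The score is the scaled excess (or deficit) of singletons relative to the
#' mutability-calibrated expectation:
#' `score = (observed singletons - expected singletons) / n`, where the
#' expectation sums the model-predicted singleton proportion over the subset's
#' contexts. Positive scores indicate singleton enrichment, i.e. stronger
#' purifying selection. The confidence interval is the Wilson score interval
#' of the observed singleton proportion, shifted by the expected proportion
#' (treated as fixed).
#'
#' @param variants variant subset carrying `context_key`, `mu`, `is_singleton`.
#' @param model a `calibration_model` from [fit_calibration()].
#' @param conf confidence level for the Wilson interval.
#' @return one-row data.frame with `score`, `ci_low`, `ci_high`,
#'   `n_variants`, `n_singletons`, `expected_singletons`.
#' @export
score_subset <- function(variants, model, conf = 0.95) {
  if (nrow(variants) == 0) stop("cannot score an empty subset")
  stopifnot(inherits(model, "calibration_model"))
  p_hat <- predict_ps(model, variants$mu)
  n <- nrow(variants)
  s_obs <- sum(variants$is_singleton)
  expected <- sum(p_hat)
  ci <- wilson_ci(s_obs, n, conf)
  data.frame(
    score = (s_obs - expected) / n,
    ci_low = ci$low - expected / n,
    ci_high = ci$high - expected / n,
    n_variants = n, n_singletons = s_obs, expected_singletons = expected
  )
}

#' Selection scores per group
#'
#' Splits the variant table on a grouping column and scores each group.
#' Rows with a missing group key are dropped (and counted in the
#' `"dropped"` attribute); groups smaller than `min_n` are flagged.
#'
#' @param variants annotated variant data.frame.
#' @param group name of the grouping column.
#' @param model a `calibration_model`.
#' @param min_n minimum group size below which the `small` flag is set.
#' @return data.frame with one row per group: the group label, the
#'   [score_subset()] columns, and `small`.
#' @export
score_by_group <- function(variants, group, model, min_n = 100) {
  stopifnot(group %in% names(variants))
  keep <- !is.na(variants[[group]])
  dropped <- sum(!keep)
  variants <- variants[keep, , drop = FALSE]
  if (nrow(variants) == 0) stop("all groups empty")
  parts <- split(variants, variants[[group]])
  rows <- lapply(names(parts), function(g) {
    cbind(data.frame(group = g, stringsAsFactors = FALSE),
          score_subset(parts[[g]], model))
  })
  out <- do.call(rbind, rows)
  out$small <- out$n_variants < min_n
  attr(out, "dropped") <- dropped
  rownames(out) <- NULL
  out
}

#' Welch contrast between the selection scores of two variant groups
#'
#' Tests whether two groups differ in singleton enrichment using a Welch
#' (unequal-variance) two-sample t test on per-context residual proportions
#' `ps_c(group) - fitted_c`, restricted to contexts with at least `min_n`
#' variants in the group. The reported difference is the difference of the
#' two group-level selection scores. p values are Bonferroni-adjusted over
#' `family_size` comparisons.
#'
#' @param group_a,group_b variant data.frames (annotated, scorable).
#' @param model a `calibration_model`.
#' @param family_size number of comparisons in the Bonferroni family.
#' @param min_n minimum variants per context for a context to enter the test.
#' @return one-row data.frame with `diff`, `statistic`, `df`, `p`, `p_adj`,
#'   `method`.
#' @export
score_contrast <- function(group_a, group_b, model, family_size = 1,
                           min_n = 20) {
  if (nrow(group_a) == 0 || nrow(group_b) == 0)
    stop("both groups must be non-empty")
  res_a <- context_residuals(group_a, model, min_n)
  res_b <- context_residuals(group_b, model, min_n)
  if (length(res_a) < 2 || length(res_b) < 2)
    stop("need at least 2 contexts with n >= ", min_n, " in each group")
  tt <- stats::t.test(res_a, res_b, var.equal = FALSE)
  d <- score_subset(group_a, model)$score - score_subset(group_b, model)$score
  data.frame(
    diff = d,
    statistic = unname(tt$statistic), df = unname(tt$parameter),
    p = tt$p.value, p_adj = min(1, tt$p.value * family_size),
    method = "Welch two-sample t test on per-context residuals",
    stringsAsFactors = FALSE
  )
}

context_residuals <- function(variants, model, min_n) {
  agg <- aggregate_contexts(variants)
  agg <- agg[agg$n >= min_n, , drop = FALSE]
  agg$ps - predict_ps(model, agg$mu)
}

#' Selection scores by mutability quartile
#'
#' Diagnostic for residual mutability bias in the calibration: contexts are
#' binned into four mutability quartiles with boundaries weighted by variant
#' count (so the quartiles hold approximately equal numbers of variants,
#' matching 0-25/25-50/50-75/75-100% labels), and each quartile is scored.
#' Under a correctly specified calibration all four scores should be
#' statistically indistinguishable from zero; the identity-transform (MAPS)
#' fit on saturation-shaped data instead shows a positive lowest-mutability
#' quartile.
#'
#' @param variants calibration-universe variants (annotated, scorable).
#' @param model a `calibration_model` fitted on the same universe.
#' @param conf confidence level.
#' @return data.frame with one row per quartile (`lowest`, `lower`, `higher`,
#'   `highest`): mutability range, and the [score_subset()] columns.
#' @export
mutability_quartile_diagnostic <- function(variants, model, conf = 0.95) {
  agg <- aggregate_contexts(variants)
  if (length(unique(agg$mu)) < 2)
    stop("degenerate mutability distribution: a single unique value")
  agg <- agg[order(agg$mu), , drop = FALSE]
  cum_frac <- (cumsum(agg$n) - agg$n / 2) / sum(agg$n)
  quart <- cut(cum_frac, breaks = c(0, 0.25, 0.5, 0.75, 1),
               labels = c("lowest", "lower", "higher", "highest"),
               include.lowest = TRUE)
  key_to_quart <- stats::setNames(as.character(quart), agg$context_key)
  variants$mu_quartile <- key_to_quart[variants$context_key]
  rows <- lapply(c("lowest", "lower", "higher", "highest"), function(q) {
    sub <- variants[variants$mu_quartile == q, , drop = FALSE]
    cbind(data.frame(quartile = q,
                     mu_min = min(sub$mu), mu_max = max(sub$mu),
                     stringsAsFactors = FALSE),
          score_subset(sub, model, conf))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Serialize or restore a calibration model
#'
#' Models are written as versioned JSON carrying the transform, coefficients
#' and per-context calibration aggregates.
#'
#' @param model a `calibration_model`.
#' @param path file path.
#' @return `path` (write) or the restored `calibration_model` (read).
#' @export
write_calibration <- function(model, path) {
  jsonlite::write_json(
    list(format = "synsel_calibration", version = 1L,
         transform = model$transform,
         intercept = model$intercept, slope = model$slope,
         aggregates = model$aggregates),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "synsel_calibration"))
    stop("not a calibration model file: ", path)
  structure(
    list(transform = obj$transform, intercept = obj$intercept,
         slope = obj$slope, aggregates = as.data.frame(obj$aggregates)),
    class = "calibration_model"
  )
}
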