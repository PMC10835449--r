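#' Build the substitution-class design matrix for predictor decomposition
#'
#' The unit of observation is the substitution class: a distinct
#' (ref codon, alt codon) pair, optionally stratified by mutational context
#' class. For each class with at least `min_n` variants, the response is the
#' class's selection score from [score_subset()] and the predictors are the
#' substitution's tAI, CSC and GC deltas, the amino acid's codon degeneracy
#' and the class's mean transformed mutability. Rows are weighted by class
#' variant count. (A variant-level response does not exist: the selection
#' score is a group statistic.)
#'
#' @param variants annotated, scorable variant data.frame.
#' @param model a `calibration_model`.
#' @param min_n minimum variants per class.
#' @param stratify_context also stratify classes by mutational context class.
#' @return An object of class `design_matrix`: data.frame with `class`, `n`
#'   (weight), `response`, and predictor columns `delta_tai`, `delta_csc`,
#'   `delta_gc`, `degeneracy`, `mean_t_mu`.
#' @export
build_design_matrix <- function(variants, model, min_n = 50,
                                stratify_context = FALSE) {
  need <- c("ref_codon", "alt_codon", "delta_tai", "delta_csc", "delta_gc",
            "degeneracy", "mu", "context_key", "is_singleton")
  stopifnot(all(need %in% names(variants)))
  key <- paste0(variants$ref_codon, ">", variants$alt_codon)
  if (stratify_context) key <- paste0(key, "|", variants$context_class)
  parts <- split(variants, key)
  parts <- parts[vapply(parts, nrow, integer(1)) >= min_n]
  dropped <- length(unique(key)) - length(parts)
  if (dropped > 0)
    message(dropped, " substitution class(es) below min_n = ", min_n,
            " excluded")
  if (length(parts) < 10)
    stop("fewer than 10 usable substitution classes")
  rows <- lapply(names(parts), function(k) {
    sub <- parts[[k]]
    data.frame(
      class = k, n = nrow(sub),
      response = score_subset(sub, model)$score,
      delta_tai = sub$delta_tai[1], delta_csc = sub$delta_csc[1],
      delta_gc = sub$delta_gc[1], degeneracy = sub$degeneracy[1],
      mean_t_mu = mean(transform_mu(sub$mu, model$transform)),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  if (anyNA(out[, c("delta_tai", "delta_csc", "delta_gc")]))
    stop("missing predictor values in retained classes")
  rownames(out) <- NULL
  structure(out, class = c("design_matrix", "data.frame"))
}

design_predictors <- function() {
  c("delta_tai", "delta_csc", "delta_gc", "degeneracy", "mean_t_mu")
}

# Weighted standardization: zero weighted mean, unit weighted variance.
standardize_weighted <- function(X, w) {
  w <- w / sum(w)
  centers <- colSums(X * w)
  Xc <- sweep(X, 2, centers)
  scales <- sqrt(colSums(Xc^2 * w))
  scales[scales == 0] <- 1
  list(X = sweep(Xc, 2, scales, "/"), centers = centers, scales = scales)
}

#' Cross-validated LASSO fit of selection scores on codon-level predictors
#'
#' Fits a weighted L1-penalized linear model of the class-level selection
#' score on the standardized predictors, choosing the penalty by K-fold
#' cross-validated prediction error. Coefficients are reported at
#' `lambda.min` (estimation) and at `lambda.min + 1SE` (the parsimonious rule
#' used for selection statements). Predictors are standardized to zero
#' weighted mean and unit weighted variance before fitting, so selection is
#' invariant to affine rescaling of any predictor.
#'
#' @param matrix a `design_matrix`.
#' @param cv_folds number of cross-validation folds (>= 3).
#' @param seed integer seed controlling the fold assignment.
#' @return An object of class `lasso_fit`: list with `lambda` (grid),
#'   `lambda_min`, `lambda_1se`, `coef_min`, `coef_1se` (on the standardized
#'   scale, intercept excluded), `selected` (predictors with nonzero
#'   coefficient at the 1SE rule), `r_squared` (weighted, at `lambda.min`),
#'   `seed`, and standardization constants.
#' @export
fit_lasso <- function(matrix, cv_folds = 10, seed = 1) {
  stopifnot(inherits(matrix, "design_matrix"), cv_folds >= 3)
  preds <- design_predictors()
  y <- matrix$response
  if (stats::sd(y) == 0) stop("constant response")
  w <- matrix$n / mean(matrix$n)
  std <- standardize_weighted(as.matrix(matrix[, preds]), matrix$n)
  set.seed(seed)
  folds <- sample(rep_len(seq_len(cv_folds), nrow(matrix)))
  cv <- glmnet::cv.glmnet(std$X, y, weights = w, alpha = 1,
                          foldid = folds, standardize = FALSE)
  coef_at <- function(s) {
    co <- as.matrix(stats::coef(cv, s = s))
    stats::setNames(co[preds, 1], preds)
  }
  coef_min <- coef_at("lambda.min")
  coef_1se <- coef_at("lambda.1se")
  fit <- structure(
    list(lambda = cv$lambda, lambda_min = cv$lambda.min,
         lambda_1se = cv$lambda.1se,
         intercept_min = as.numeric(stats::coef(cv, s = "lambda.min")[1]),
         coef_min = coef_min, coef_1se = coef_1se,
         selected = names(coef_1se)[coef_1se != 0],
         centers = std$centers, scales = std$scales,
         seed = seed, glmnet = cv),
    class = "lasso_fit"
  )
  fit$r_squared <- variance_explained(fit, matrix)
  fit
}

#' @export
print.lasso_fit <- function(x, ...) {
  cat("<lasso_fit>\n")
  cat("  lambda.min =", signif(x$lambda_min, 4),
      " lambda.1se =", signif(x$lambda_1se, 4), "\n")
  cat("  selected (1SE):",
      if (length(x$selected)) paste(x$selected, collapse = ", ")
      else "(none)", "\n")
  cat("  weighted R^2 (lambda.min):", round(x$r_squared, 4), "\n")
  invisible(x)
}

#' Weighted variance explained by a LASSO fit
#'
#' Weighted R-squared of the fitted versus observed class-level responses at
#' `lambda.min`, with weights equal to class variant counts.
#'
#' @param fit a `lasso_fit`.
#' @param matrix the `design_matrix` it was fitted on.
#' @return R-squared in \[0, 1\] (truncated at 0 if the penalized fit does
#'   worse than the weighted mean).
#' @export
variance_explained <- function(fit, matrix) {
  stopifnot(inherits(fit, "lasso_fit"), inherits(matrix, "design_matrix"))
  preds <- design_predictors()
  X <- as.matrix(matrix[, preds])
  if (nrow(X) != length(matrix$response)) stop("mismatched dimensions")
  Xs <- sweep(sweep(X, 2, fit$centers), 2, fit$scales, "/")
  y_hat <- fit$intercept_min + as.numeric(Xs %*% fit$coef_min)
  w <- matrix$n / sum(matrix$n)
  y <- matrix$response
  y_bar <- sum(w * y)
  ss_res <- sum(w * (y - y_hat)^2)
  ss_tot <- sum(w * (y - y_bar)^2)
  max(0, 1 - ss_res / ss_tot)
}

#' Serialize or restore a LASSO fit
#'
#' JSON round-trip of the fit's seed, lambda path, chosen lambdas,
#' coefficients and standardization constants (the internal glmnet object is
#' not serialized).
#'
#' @param fit a `lasso_fit`.
#' @param path file path.
#' @return `path` (write) or the restored `lasso_fit` (read).
#' @export
write_lasso_fit <- function(fit, path) {
  keep <- c("lambda", "lambda_min", "lambda_1se", "intercept_min",
            "coef_min", "coef_1se", "selected", "centers", "scales",
            "seed", "r_squared")
  obj <- fit[keep]
  obj$format <- "synsel_lasso"
  obj$version <- 1L
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_lasso_fit
#' @export
read_lasso_fit <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "synsel_lasso"))
    stop("not a lasso fit file: ", path)
  obj$format <- obj$version <- NULL
  structure(obj, class = "lasso_fit")
}
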