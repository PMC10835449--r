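test_that("context aggregation counts singletons per context", {
  v <- toy_variants(mu = c(0.1, 0.2), n = c(3, 4), s = c(2, 1))
  agg <- aggregate_contexts(v)
  expect_equal(agg$n, c(3L, 4L))
  expect_equal(agg$s, c(2L, 1L))
  expect_equal(agg$ps, c(2 / 3, 1 / 4))
  expect_equal(sum(agg$n), nrow(v))

  # duplicating every variant doubles n, leaves ps unchanged
  agg2 <- aggregate_contexts(rbind(v, v))
  expect_equal(agg2$ps, agg$ps)
  expect_equal(agg2$n, 2L * agg$n)
  expect_error(aggregate_contexts(v[0, ]), "no variants")
})

test_that("two contexts determine the calibration line exactly", {
  # points (0.1, 0.4) and (0.2, 0.6) -> alpha 0.2, beta 2
  agg <- data.frame(context_key = c("a", "b"), mu = c(0.1, 0.2),
                    context_class = "transversion", n = c(10L, 20L),
                    s = c(4L, 12L), ps = c(0.4, 0.6))
  m <- fit_calibration(agg, "identity")
  expect_equal(m$intercept, 0.2, tolerance = 1e-12)
  expect_equal(m$slope, 2, tolerance = 1e-12)
  expect_equal(m$aggregates$residual, c(0, 0), tolerance = 1e-12)

  # sqrt transform turns mu {0.01, 0.04} into regressors {0.1, 0.2}
  agg_sq <- agg
  agg_sq$mu <- c(0.01, 0.04)
  m_sq <- fit_calibration(agg_sq, "sqrt")
  expect_equal(m_sq$intercept, 0.2, tolerance = 1e-12)
  expect_equal(m_sq$slope, 2, tolerance = 1e-12)

  expect_error(fit_calibration(agg[1, ]), "2 distinct")
  agg_bad <- agg; agg_bad$mu[1] <- -0.1
  expect_error(fit_calibration(agg_bad), "positive")
})

test_that("weighted calibration matches the closed-form WLS oracle", {
  agg <- data.frame(
    context_key = letters[1:4], mu = c(0.01, 0.04, 0.09, 0.25),
    context_class = "transversion", n = c(100L, 50L, 200L, 25L),
    s = c(55L, 25L, 84L, 8L), ps = c(0.55, 0.50, 0.42, 0.32))
  m <- fit_calibration(agg, "sqrt")
  # normal equations: (X' W X)^-1 X' W y with X = [1, sqrt(mu)]
  X <- cbind(1, sqrt(agg$mu))
  W <- diag(agg$n)
  beta <- solve(t(X) %*% W %*% X, t(X) %*% W %*% agg$ps)
  expect_equal(m$intercept, beta[1, 1], tolerance = 1e-10)
  expect_equal(m$slope, beta[2, 1], tolerance = 1e-10)
  # weighted residuals sum to zero (intercept present)
  expect_lt(abs(sum(agg$n * m$aggregates$residual)), 1e-10)
})

test_that("scoring matches the worked two-context example", {
  # model alpha = 0.2, beta = 2 on identity transform; subset of 50 + 50
  # variants at t(mu) = {0.1, 0.2} with 55 singletons:
  # expected = 50 * 0.4 + 50 * 0.6 = 50, score = (55 - 50) / 100 = 0.05
  m <- toy_model(0.2, 2)
  v <- toy_variants(mu = c(0.1, 0.2), n = c(50, 50), s = c(25, 30))
  sc <- score_subset(v, m)
  expect_equal(sc$expected_singletons, 50)
  expect_equal(sc$n_singletons, 55)
  expect_equal(sc$score, 0.05)
  expect_true(sc$ci_low <= sc$score && sc$score <= sc$ci_high)

  # a subset matching the model predictions exactly scores 0
  v0 <- toy_variants(mu = c(0.1, 0.2), n = c(50, 50), s = c(20, 30))
  expect_equal(score_subset(v0, m)$score, 0)
  expect_error(score_subset(v[0, ], m), "empty")
})

test_that("scoring the full calibration set gives exactly zero", {
  ds <- small_dataset()
  sc <- score_subset(ds$annotated, ds$model)
  expect_lt(abs(sc$score), 1e-10)
})

test_that("score is replication invariant and monotone in singletons", {
  m <- toy_model(0.2, 2)
  v <- toy_variants(mu = c(0.1, 0.2), n = c(40, 60), s = c(20, 30))
  sc <- score_subset(v, m)
  sc_rep <- score_subset(v[rep(seq_len(nrow(v)), 3), ], m)
  expect_equal(sc_rep$score, sc$score, tolerance = 1e-12)

  scores <- sapply(20:30, function(s1) {
    score_subset(toy_variants(c(0.1, 0.2), c(40, 60), c(s1, 30)), m)$score
  })
  expect_true(all(diff(scores) > 0))
})

test_that("group scoring partitions the input and ignores order", {
  ds <- small_dataset()
  v <- ds$annotated
  by_opt <- score_by_group(v, "optimality", ds$model)
  expect_equal(sum(by_opt$n_variants), nrow(v))
  shuffled <- v[sample(nrow(v)), ]
  by_opt2 <- score_by_group(shuffled, "optimality", ds$model)
  expect_equal(by_opt, by_opt2, ignore_attr = TRUE)
  # missing keys are dropped and counted
  v$optimality[1:10] <- NA
  by_opt3 <- score_by_group(v, "optimality", ds$model)
  expect_equal(attr(by_opt3, "dropped"), 10)
  expect_equal(sum(by_opt3$n_variants), nrow(v) - 10)
})

test_that("Welch contrast is null for identical groups and honors family size", {
  ds <- small_dataset()
  v <- ds$annotated
  ct <- score_contrast(v, v, ds$model)
  expect_equal(ct$diff, 0)
  expect_equal(ct$p_adj, ct$p)
  ct5 <- score_contrast(v, v, ds$model, family_size = 5)
  expect_equal(ct5$p_adj, min(1, 5 * ct5$p))
  expect_error(score_contrast(v[0, ], v, ds$model), "non-empty")
})

test_that("a planted offset separates groups in the Welch contrast", {
  # 10,000 variants per group over shared contexts; group A gets +0.05
  # singleton probability on top of the neutral curve
  set.seed(31)
  hits <- replicate(20, {
    mus <- runif(20, 0.05, 0.9)
    p0 <- 0.55 - 0.25 * sqrt(mus)
    n_per <- 500
    mk <- function(p_extra) {
      s <- rbinom(length(mus), n_per, p0 + p_extra)
      do.call(rbind, lapply(seq_along(mus), function(i) {
        data.frame(context_key = paste0("c", i),
                   context_class = "transversion", mu = mus[i],
                   is_singleton = rep(c(TRUE, FALSE),
                                      c(s[i], n_per - s[i])))
      }))
    }
    m <- fit_calibration(aggregate_contexts(mk(0)), "sqrt")
    ct <- score_contrast(mk(0.05), mk(0), m)
    ct$p < 0.05 && ct$diff > 0
  })
  expect_gte(mean(hits), 0.95)
})

test_that("mutability quartiles hold equal variant counts and sum to total", {
  ds <- small_dataset()
  q <- mutability_quartile_diagnostic(ds$annotated, ds$model)
  expect_equal(q$quartile, c("lowest", "lower", "higher", "highest"))
  expect_equal(sum(q$n_variants), nrow(ds$annotated))
  expect_lt(max(q$n_variants) / min(q$n_variants), 1.3)
  expect_true(all(diff(q$mu_min) > 0))
  v1 <- toy_variants(0.1, 50, 20)
  m <- toy_model(0.2, 2)
  expect_error(mutability_quartile_diagnostic(v1, m), "degenerate")
})

test_that("calibration models serialize and restore losslessly", {
  ds <- small_dataset()
  path <- withr::local_tempfile(fileext = ".json")
  write_calibration(ds$model, path)
  back <- read_calibration(path)
  expect_equal(back$intercept, ds$model$intercept)
  expect_equal(back$slope, ds$model$slope)
  expect_equal(back$transform, ds$model$transform)
  v <- ds$annotated[1:500, ]
  expect_equal(score_subset(v, back)$score, score_subset(v, ds$model)$score)
})
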