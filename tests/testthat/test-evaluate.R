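test_that("concordance handles the canonical small cases", {
  expect_equal(c_index(c(1, 2, 3), c(1, 2, 3)), 1.0)
  expect_equal(c_index(c(3, 2, 1), c(1, 2, 3)), 0.0)
  expect_equal(c_index(c(2, 2, 2), c(1, 2, 3)), 0.5)
  expect_error(c_index(c(1, 2), c(4, 4)), "undefined")
})

test_that("concordance matches the exhaustive pair-counting oracle", {
  set.seed(13)
  for (i in 1:40) {
    n <- sample(3:30, 1)
    y <- sample(-4:2, n, replace = TRUE)
    if (length(unique(y)) < 2) next
    p <- round(rnorm(n), sample(0:1, 1))  # rounding induces tied predictions
    expect_identical(c_index(p, y), c_index_oracle(p, y))
  }
})

test_that("concordance agrees with the survival package's estimator", {
  set.seed(14)
  for (i in 1:5) {
    n <- 40
    y <- round(rnorm(n), 1)
    p <- round(y + rnorm(n), 1)
    ours <- c_index(p, y)
    theirs <- survival::concordance(y ~ p)$concordance
    expect_equal(ours, theirs, tolerance = 1e-12)
  }
})

test_that("concordance is invariant to monotone transforms and flips", {
  set.seed(15)
  y <- sample(-3:1, 40, replace = TRUE)
  p <- rnorm(40)
  base <- c_index(p, y)
  expect_equal(c_index(exp(2 * p) - 5, y), base)
  expect_equal(c_index(rank(p), y), base)
  expect_equal(c_index(-p, y), 1 - base)  # tie-free predictions
})

test_that("bootstrap intervals: seeded, collapse at B=1, tighten with n", {
  set.seed(16)
  y <- round(rnorm(200), 1)
  p <- y + rnorm(200)
  ci1 <- bootstrap_ci(p, y, eval_config(200, seed = 4))
  ci2 <- bootstrap_ci(p, y, eval_config(200, seed = 4))
  expect_identical(ci1, ci2)
  expect_true(ci1$low <= ci1$estimate && ci1$estimate <= ci1$high)
  one <- bootstrap_ci(p, y, eval_config(1, seed = 4))
  expect_equal(one$low, one$high)
  # width decreases with n (averaged over a few seeds)
  widths <- vapply(1:5, function(s) {
    set.seed(s)
    yb <- round(rnorm(400), 1)
    pb <- yb + rnorm(400)
    w400 <- with(bootstrap_ci(pb, yb, eval_config(200, seed = s)),
                 high - low)
    w100 <- with(bootstrap_ci(pb[1:100], yb[1:100],
                              eval_config(200, seed = s)), high - low)
    w400 < w100
  }, logical(1))
  expect_gte(mean(widths), 0.8)
})

test_that("degenerate resamples are skipped, counted, and bounded", {
  set.seed(18)
  y <- c(rep(0, 39), 1)  # resamples missing the lone 1 are degenerate
  p <- rnorm(40)
  ci <- bootstrap_ci(p, y, eval_config(200, seed = 2))
  expect_lt(ci$b_used, 200)
  expect_gt(ci$b_used, 100)
  # a two-subject cohort loses over half its resamples to ties
  expect_error(bootstrap_ci(c(0.1, 0.9), c(0, 1), eval_config(100, seed = 1)),
               "degenerate")
})

test_that("lasso calibration recovers exact lines and shrinks fully", {
  x <- 1:10
  cal <- calibrate(x, 2 * x + 1, lambda = 0)
  expect_equal(cal$slope, 2)
  expect_equal(cal$intercept, 1)
  big <- calibrate(x, 2 * x + 1, lambda = 1e6)
  expect_equal(big$slope, 0)
  expect_equal(big$intercept, mean(2 * x + 1))
  expect_error(calibrate(rep(1, 5), 1:5), "constant")
})

test_that("lasso calibration matches an independent numerical solver", {
  set.seed(17)
  for (i in 1:10) {
    x <- rnorm(60)
    y <- 0.8 * x + rnorm(60, sd = 0.5)
    lam <- sample(c(0.01, 0.05, 0.3), 1)
    cal <- calibrate(x, y, lambda = lam)
    orc <- lasso_oracle(x, y, lam)
    expect_lt(abs(cal$slope - orc[["slope"]]), 1e-6)
    expect_lt(abs(cal$intercept - orc[["intercept"]]), 1e-6)
  }
})

test_that("fit metrics follow their definitions", {
  y <- c(-2, -1, 0, 3)
  perfect <- structure(list(slope = 1, intercept = 0, lambda = 0),
                       class = "calibration_model")
  fm <- fit_metrics(perfect, y, y)
  expect_equal(fm$r_squared, 1)
  expect_equal(fm$mae, 0)
  flat <- structure(list(slope = 0, intercept = mean(y), lambda = 0),
                    class = "calibration_model")
  fm0 <- fit_metrics(flat, rnorm(4), y)
  expect_equal(fm0$r_squared, 0)
  # hand-computed four-point case: calibrated yhat = 0.5 * p + 1
  p <- c(0, 2, 4, 6)
  cal <- structure(list(slope = 0.5, intercept = 1, lambda = 0),
                   class = "calibration_model")
  yhat <- 0.5 * p + 1
  fm4 <- fit_metrics(cal, p, y)
  expect_equal(fm4$mae, mean(abs(y - yhat)))
  expect_equal(fm4$r_squared,
               1 - sum((y - yhat)^2) / sum((y - mean(y))^2))
  expect_error(fit_metrics(cal, p, rep(1, 4)), "zero outcome variance")
})

test_that("paired C-index differences behave at the extremes", {
  y <- c(1, 2, 3, 4, 5, 6)
  same <- delta_c_index(y, y, y, eval_config(200, seed = 5))
  expect_equal(same$delta_c, 0)
  expect_true(same$low <= 0 && same$high >= 0)
  expect_false(same$significant)
  extreme <- delta_c_index(y, -y, y, eval_config(200, seed = 5))
  expect_equal(extreme$delta_c, 1.0)
  expect_error(delta_c_index(y, y[-1], y, eval_config(10, seed = 1)))
})

test_that("BCa intervals are available and bracket the estimate", {
  set.seed(19)
  y <- round(rnorm(150), 1)
  p <- y + rnorm(150)
  pct <- bootstrap_ci(p, y, eval_config(300, seed = 6))
  bca <- bootstrap_ci(p, y, eval_config(300, seed = 6), type = "bca")
  expect_true(bca$low <= bca$estimate && bca$estimate <= bca$high)
  expect_equal(bca$estimate, pct$estimate)
  expect_identical(bca, bootstrap_ci(p, y, eval_config(300, seed = 6),
                                     type = "bca"))
})
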