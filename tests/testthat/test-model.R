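test_that("feature-combination enumeration is exhaustive and ordered", {
  full <- enumerate_feature_combinations()
  expect_length(full, 2 * 31 * 4)
  expect_length(enumerate_feature_combinations(bands = c("alpha", "beta")),
                2 * 3 * 4)
  expect_length(enumerate_feature_combinations(power_types = "absolute",
                                               bands = "alpha",
                                               region_filters = "occipital"),
                1)
  labels <- vapply(full, format, character(1))
  expect_false(anyDuplicated(labels) > 0)
  expect_true(all(vapply(full, function(cc) length(cc$bands) > 0,
                         logical(1))))
  # absolute power types come first, then relative
  expect_equal(unique(vapply(full, `[[`, character(1), "power_type")),
               c("absolute", "relative"))
})

test_that("stratified folds balance sizes and class proportions", {
  set.seed(1)
  y <- sample(rep(-3:1, c(120, 150, 130, 80, 38)))  # n = 518
  folds <- stratified_folds(y, cv_config(5, seed = 2))
  sizes <- tabulate(folds, 5)
  expect_setequal(unique(sizes), c(103L, 104L))
  expect_equal(sum(sizes), 518L)
  # per-class proportional within +-1 of an even split
  for (v in unique(y)) {
    per_fold <- tabulate(folds[y == v], 5)
    expect_lte(diff(range(per_fold)), 1)
  }
  # forced allocation: 2 classes of 5, k = 5 -> one of each per fold
  y2 <- rep(c(0, 1), each = 5)
  f2 <- stratified_folds(y2, cv_config(5, seed = 3))
  for (f in 1:5) expect_equal(sort(y2[f2 == f]), c(0, 1))
  # determinism and partition property
  expect_identical(folds, stratified_folds(y, cv_config(5, seed = 2)))
  expect_error(stratified_folds(1:3, cv_config(5)), "at least")
})

test_that("undersized outcome classes merge into nearest-valued classes", {
  y <- c(rep(0, 20), rep(1, 20), 5)  # the lone 5 cannot fill 5 folds
  folds <- stratified_folds(y, cv_config(5, seed = 1))
  expect_equal(sort(unique(folds)), 1:5)
  expect_lte(diff(range(tabulate(folds, 5))), 1)
})

test_that("a perfectly rank-correlated feature reaches training C of 1", {
  x <- matrix(seq_len(30), ncol = 1, dimnames = list(NULL, "only"))
  y <- 2 * as.numeric(x[, 1]) - 7  # monotone in x, well separated
  fit <- fit_gbdt(x, y, tree_params(60, 5, 32, learning_rate = 0.3,
                                    seed = 1))
  expect_equal(c_index(predict(fit, x), y), 1.0)
})

test_that("degenerate fits are refused and stumps stay piecewise-flat", {
  x <- matrix(rnorm(20), ncol = 1, dimnames = list(NULL, "f"))
  expect_error(fit_gbdt(x, rep(1, 20), tree_params()), "constant")
  stump <- fit_gbdt(x, rnorm(20), tree_params(1, 1, 2, seed = 1))
  expect_lte(length(unique(predict(stump, x))), 2L)
})

test_that("pooled CV gives each subject one out-of-fold prediction", {
  set.seed(4)
  x <- matrix(rnorm(60 * 3), 60, 3,
              dimnames = list(NULL, paste0("f", 1:3)))
  y <- round(x[, 1] + rnorm(60, sd = 0.5))
  folds <- stratified_folds(y, cv_config(5, 5))
  cvfit <- pooled_cv_predict(x, y, tree_params(20, 3, 7), folds)
  expect_false(anyNA(cvfit$predictions))
  expect_length(cvfit$predictions, 60)
  cvfit2 <- pooled_cv_predict(x, y, tree_params(20, 3, 7), folds)
  expect_identical(cvfit$predictions, cvfit2$predictions)
})

test_that("leave-one-out pooled CV matches the per-subject exclusion oracle", {
  set.seed(6)
  n <- 12
  x <- matrix(rnorm(n * 2), n, 2, dimnames = list(NULL, c("a", "b")))
  y <- round(2 * x[, 1] + rnorm(n, sd = 0.3), 1)
  params <- tree_params(10, 2, 4, seed = 2)
  cvfit <- pooled_cv_predict(x, y, params, folds = seq_len(n))
  oracle <- vapply(seq_len(n), function(i) {
    fit <- fit_gbdt(x[-i, , drop = FALSE], y[-i], params)
    predict(fit, x[i, , drop = FALSE])
  }, numeric(1))
  expect_equal(cvfit$predictions, oracle)
})

test_that("validation outcomes never leak into a fold's predictions", {
  set.seed(7)
  n <- 50
  x <- matrix(rnorm(n * 3), n, 3, dimnames = list(NULL, paste0("f", 1:3)))
  y <- round(x[, 1] + rnorm(n, sd = 0.5))
  folds <- rep(1:5, each = 10)
  params <- tree_params(15, 3, 7, seed = 1)
  base <- pooled_cv_predict(x, y, params, folds)
  y_corrupt <- y
  y_corrupt[folds == 2] <- rev(y[folds == 2]) + 5
  corrupted <- pooled_cv_predict(x, y_corrupt, params, folds)
  expect_identical(base$predictions[folds == 2],
                   corrupted$predictions[folds == 2])
})

test_that("permuted outcomes give chance-level out-of-fold concordance", {
  set.seed(8)
  n <- 300
  x <- matrix(rnorm(n * 5), n, 5, dimnames = list(NULL, paste0("f", 1:5)))
  y <- sample(round(x[, 1] * 1.2 + rnorm(n, sd = 0.6)))  # permuted
  folds <- stratified_folds(y, cv_config(5, 9))
  cvfit <- pooled_cv_predict(x, y, tree_params(50, 3, 7), folds)
  ci <- c_index(cvfit$predictions, y)
  expect_gt(ci, 0.4)
  expect_lt(ci, 0.6)
})

test_that("the search returns the concordance-maximising pair", {
  scores <- make_scores(60, seed = 10)
  bands <- fake_band_table(60, seed = 10)
  # plant a monotone association between occipital alpha and item-1 change
  oz <- bands$absolute[bands$site == "Oz" & bands$band == "alpha"]
  imp <- -as.integer(cut(oz, quantile(oz, 0:4 / 4), include.lowest = TRUE))
  scores$baseline_01 <- 4L
  scores$week8_01 <- 4L + imp
  combos <- list(
    feature_combination("absolute", "beta", "occipital"),
    feature_combination("absolute", "alpha", "occipital"))
  grid <- param_grid(50, 3, 7)
  res <- tune_symptom_model(scores, bands, item = 1, combos = combos,
                            grid = grid, mode = "eeg",
                            cv = cv_config(5, 1),
                            cfg = eval_config(50, seed = 1))
  expect_true("alpha" %in% res$combination$bands)
  # monotone search: the winner dominates the evaluated log
  expect_gte(res$c_index, max(res$search$c_index))
  expect_equal(res$c_index, max(res$search$c_index))
  # single-pair search returns that pair
  one <- tune_symptom_model(scores, bands, item = 1, combos = combos[2],
                            grid = grid, mode = "eeg",
                            cv = cv_config(5, 1),
                            cfg = eval_config(50, seed = 1))
  expect_equal(format(one$combination), format(combos[[2]]))
  expect_equal(nrow(one$search), 1L)
})

test_that("ties in the search resolve to the earlier enumeration entry", {
  scores <- make_scores(40, seed = 11)
  bands <- fake_band_table(40, seed = 11)
  combo <- feature_combination("absolute", "alpha", "occipital")
  res <- tune_symptom_model(scores, bands, item = 2,
                            combos = list(combo, combo),
                            grid = param_grid(20, 3, 7), mode = "eeg",
                            cv = cv_config(5, 2),
                            cfg = eval_config(20, seed = 2))
  expect_equal(nrow(res$search), 2L)
  expect_equal(res$search$c_index[1], res$search$c_index[2])
  expect_equal(res$c_index, res$search$c_index[1])
})

test_that("input modes assemble the documented design matrices", {
  scores <- make_scores(30, seed = 12)
  bands <- fake_band_table(30, seed = 12)
  combos <- list(feature_combination("absolute", "alpha", "occipital"))
  grid <- param_grid(10, 3, 7)
  hrsd <- tune_symptom_model(scores, item = 3, mode = "hrsd", grid = grid,
                             cv = cv_config(5, 3),
                             cfg = eval_config(20, seed = 3))
  expect_equal(ncol(hrsd$design), 1 + 21)
  expect_true(all(grepl("^baseline ", names(hrsd$design)[-1])))
  both <- tune_symptom_model(scores, bands, item = 3, combos = combos,
                             grid = grid, cv = cv_config(5, 3),
                             cfg = eval_config(20, seed = 3))
  expect_equal(ncol(both$design), 1 + 3 + 21)
  trt <- tune_symptom_model(scores, bands, item = 3, combos = combos,
                            grid = grid, cv = cv_config(5, 3),
                            cfg = eval_config(20, seed = 3),
                            include_treatment = TRUE)
  expect_equal(ncol(trt$design), 1 + 3 + 21 + 3)
  expect_equal(trt$input_mode, "eeg_hrsd+treatment")
  expect_setequal(
    unlist(trt$design[grepl("^treatment ", names(trt$design))]) |> unique(),
    c(0L, 1L))
})

test_that("tree parameter validation enforces the leaf bound", {
  expect_error(tree_params(10, 3, 31), "exceeds")
  grid <- param_grid()
  expect_true(all(grid$num_leaves <= 2^grid$max_depth))
  expect_equal(nrow(grid), 15L)  # 3 estimators x {3:7, 5:7, 5:31, 7:7, 7:31}
})
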