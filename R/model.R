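#' Enumerate the EEG feature-combination search space
#'
#' Deterministic, duplicate-free enumeration: power type first (absolute then
#' relative), then every nonempty subset of the requested bands (by
#' increasing subset size, then canonical band order), then the region
#' options in fixed order (`all`, `frontal`, `occipital`,
#' `frontal+occipital`).  Asymmetry/ratio flags are properties of the space,
#' not enumerated axes.
#'
#' @param power_types Character subset of `c("absolute", "relative")`.
#' @param bands Character subset of the five canonical bands.
#' @param region_filters Character subset of the region options.
#' @param include_asymmetry,include_beta_alpha_ratio Flags applied to every
#'   combination.
#' @return A list of [feature_combination()] objects in enumeration order.
#' @export
#' @examples
#' length(enumerate_feature_combinations())  # 2 x 31 x 4 = 248
enumerate_feature_combinations <- function(
    power_types = c("absolute", "relative"),
    bands = eeg_bands()$band,
    region_filters = region_filter_levels(),
    include_asymmetry = FALSE,
    include_beta_alpha_ratio = FALSE) {
  stopifnot(length(bands) > 0, all(bands %in% eeg_bands()$band),
            all(power_types %in% c("absolute", "relative")),
            all(region_filters %in% region_filter_levels()))
  bands <- eeg_bands()$band[eeg_bands()$band %in% bands]
  subsets <- unlist(lapply(seq_along(bands), function(size) {
    utils::combn(bands, size, simplify = FALSE)
  }), recursive = FALSE)
  out <- list()
  for (pt in power_types) {
    for (bs in subsets) {
      for (rf in region_filters) {
        out[[length(out) + 1L]] <- feature_combination(
          pt, bs, rf, include_asymmetry, include_beta_alpha_ratio)
      }
    }
  }
  out
}

#' Boosted-tree hyperparameters
#'
#' @param n_estimators Number of boosting rounds.
#' @param max_depth Maximum tree depth.
#' @param num_leaves Maximum leaves per tree; must satisfy
#'   `num_leaves <= 2^max_depth`.
#' @param learning_rate Shrinkage per round.
#' @param seed Seed passed to the tree learner.
#' @return A `tree_params` object.
#' @export
tree_params <- function(n_estimators = 100, max_depth = 5, num_leaves = 31,
                        learning_rate = 0.1, seed = 0L) {
  stopifnot(n_estimators >= 1, max_depth >= 1, num_leaves >= 2,
            learning_rate > 0)
  if (num_leaves > 2^max_depth) {
    stop("num_leaves (", num_leaves, ") exceeds 2^max_depth (",
         2^max_depth, ")", call. = FALSE)
  }
  structure(list(n_estimators = as.integer(n_estimators),
                 max_depth = as.integer(max_depth),
                 num_leaves = as.integer(num_leaves),
                 learning_rate = learning_rate, seed = as.integer(seed)),
            class = "tree_params")
}

#' Default hyperparameter grid
#'
#' Cross of `n_estimators` x `max_depth` x `num_leaves`, restricted to valid
#' rows (`num_leaves <= 2^max_depth`); `learning_rate` is held fixed.
#'
#' @inheritParams tree_params
#' @return A tibble, one row per grid point, in enumeration order.
#' @export
param_grid <- function(n_estimators = c(50, 100, 200),
                       max_depth = c(3, 5, 7),
                       num_leaves = c(7, 31),
                       learning_rate = 0.1) {
  grid <- tidyr::expand_grid(n_estimators = as.integer(n_estimators),
                             max_depth = as.integer(max_depth),
                             num_leaves = as.integer(num_leaves))
  grid$learning_rate <- learning_rate
  grid[grid$num_leaves <= 2^grid$max_depth, ]
}

#' Cross-validation configuration
#'
#' @param k Number of folds (default 5).
#' @param seed Seed for the fold assignment.
#' @return A `cv_config` object.
#' @export
cv_config <- function(k = 5, seed = 42L) {
  stopifnot(k >= 2)
  structure(list(k = as.integer(k), seed = as.integer(seed)),
            class = "cv_config")
}

#' Stratified fold assignment for an integer-valued outcome
#'
#' Partitions subjects into `k` folds of near-equal size (differing by at
#' most one) such that each outcome class is spread across folds in
#' near-proportional counts.  Classes are the distinct outcome values;
#' classes with fewer than `k` members are merged into the nearest-valued
#' class before assignment.  Deterministic given the seed.
#'
#' @param outcomes Numeric vector of per-subject outcomes.
#' @param cv A [cv_config()].
#' @return Integer vector of fold labels (1..k) aligned to `outcomes`.
#' @export
stratified_folds <- function(outcomes, cv = cv_config()) {
  stopifnot(inherits(cv, "cv_config"))
  n <- length(outcomes)
  k <- cv$k
  if (n < k) stop("need at least k = ", k, " subjects", call. = FALSE)
  # merge undersized classes into the nearest-valued class
  class_of <- as.numeric(outcomes)
  repeat {
    tab <- table(class_of)
    vals <- as.numeric(names(tab))
    small <- which(tab < k)
    if (length(small) == 0 || length(vals) == 1) break
    v <- vals[small[which.min(tab[small])]]
    others <- vals[vals != v]
    nearest <- others[which.min(abs(others - v))]
    class_of[class_of == v] <- nearest
  }
  folds <- integer(n)
  sizes <- integer(k)
  with_seed(cv$seed, {
    for (v in sort(unique(class_of))) {
      members <- which(class_of == v)
      members <- members[sample.int(length(members))]
      targets <- rep_len(order(sizes, seq_len(k)), length(members))
      folds[members] <- targets
      sizes <- tabulate(folds[folds > 0L], nbins = k)
    }
  })
  folds
}

#' Fit a squared-error gradient-boosted tree ensemble
#'
#' Thin wrapper around a histogram-based GBDT learner (leaf-bounded,
#' depth-bounded trees; single-threaded, so deterministic given the seed)
#' with the ensemble's tree structure available for Shapley attribution.
#'
#' @param features A data frame or numeric matrix of predictors (a
#'   `subject_id` column is carried along, not used as a predictor).
#' @param outcomes Numeric outcome vector (at least two distinct values).
#' @param params A [tree_params()].
#' @return A `gbdt_fit` object.
#' @export
fit_gbdt <- function(features, outcomes, params = tree_params()) {
  stopifnot(inherits(params, "tree_params"))
  x <- as_feature_matrix(features)
  stopifnot(nrow(x) == length(outcomes))
  if (length(unique(outcomes)) < 2) {
    stop("degenerate fit: outcome is constant", call. = FALSE)
  }
  if (anyNA(x)) stop("missing feature values", call. = FALSE)
  name_map <- sanitize_names(colnames(x))
  colnames(x) <- names(name_map)
  dtrain <- xgboost::xgb.DMatrix(x, label = outcomes, nthread = 1)
  booster <- xgboost::xgb.train(
    params = list(objective = "reg:squarederror",
                  eta = params$learning_rate,
                  max_depth = params$max_depth,
                  max_leaves = params$num_leaves,
                  grow_policy = "lossguide",
                  tree_method = "hist",
                  base_score = mean(outcomes),
                  nthread = 1, seed = params$seed),
    data = dtrain, nrounds = params$n_estimators, verbose = 0)
  structure(list(booster = booster, name_map = name_map, params = params,
                 base_score = mean(outcomes)),
            class = "gbdt_fit")
}

as_feature_matrix <- function(features) {
  if (is.matrix(features)) {
    if (is.null(colnames(features))) {
      colnames(features) <- paste0("x", seq_len(ncol(features)))
    }
    return(features)
  }
  features <- as.data.frame(features, check.names = FALSE)
  features$subject_id <- NULL
  as.matrix(features)
}

#' @export
print.gbdt_fit <- function(x, ...) {
  cat(sprintf("<gbdt_fit> %d trees, depth<=%d, leaves<=%d, %d features\n",
              x$params$n_estimators, x$params$max_depth,
              x$params$num_leaves, length(x$name_map)))
  invisible(x)
}

#' @export
predict.gbdt_fit <- function(object, newdata, ...) {
  x <- as_feature_matrix(newdata)
  x <- x[, object$name_map, drop = FALSE]
  colnames(x) <- names(object$name_map)
  stats::predict(object$booster, xgboost::xgb.DMatrix(x, nthread = 1), ...)
}

#' Pooled out-of-fold cross-validated predictions
#'
#' For each fold, fits the ensemble on the remaining folds and predicts the
#' held-out subjects; predictions are pooled in input order so every subject
#' receives exactly one prediction from a model that never saw it.
#'
#' @inheritParams fit_gbdt
#' @param folds Integer fold labels from [stratified_folds()] (or any
#'   partition).
#' @return A `cv_fit`: list with `predictions` (aligned numeric vector),
#'   `fits` (per-fold `gbdt_fit`s) and `folds`.
#' @export
pooled_cv_predict <- function(features, outcomes, params = tree_params(),
                              folds) {
  x <- as_feature_matrix(features)
  stopifnot(length(folds) == nrow(x), length(outcomes) == nrow(x))
  preds <- rep(NA_real_, nrow(x))
  fits <- list()
  for (f in sort(unique(folds))) {
    hold <- folds == f
    fit <- fit_gbdt(x[!hold, , drop = FALSE], outcomes[!hold], params)
    preds[hold] <- predict(fit, x[hold, , drop = FALSE])
    fits[[as.character(f)]] <- fit
  }
  structure(list(predictions = preds, fits = fits, folds = folds),
            class = "cv_fit")
}
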