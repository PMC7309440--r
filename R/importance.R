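#' Shapley attributions for a fitted tree ensemble
#'
#' Exact per-subject, per-feature Shapley values under the tree-conditional
#' expectation convention (TreeSHAP): feature credit is the change in the
#' expected model output when the feature's value is revealed, averaged over
#' all orderings.  Attributions satisfy local accuracy: for every subject,
#' `base_value + sum(attributions) = prediction`.
#'
#' @param fit A [fit_gbdt()] model.
#' @param features Feature table or matrix matching the training schema.
#' @return An `attribution_matrix`: list with `attributions` (subjects x
#'   features matrix, original feature names), `base_value` (per-subject
#'   expected model output) and `predictions`.
#' @export
tree_shap <- function(fit, features) {
  stopifnot(inherits(fit, "gbdt_fit"))
  x <- as_feature_matrix(features)
  missing_feats <- setdiff(unname(fit$name_map), colnames(x))
  if (length(missing_feats) > 0) {
    stop("feature table does not match the training schema; missing: ",
         paste(missing_feats, collapse = ", "), call. = FALSE)
  }
  x <- x[, unname(fit$name_map), drop = FALSE]
  colnames(x) <- names(fit$name_map)
  dmat <- xgboost::xgb.DMatrix(x, nthread = 1)
  contrib <- stats::predict(fit$booster, dmat, predcontrib = TRUE)
  bias_col <- ncol(contrib)
  attr_mat <- contrib[, -bias_col, drop = FALSE]
  colnames(attr_mat) <- unname(fit$name_map)
  structure(list(attributions = attr_mat,
                 base_value = contrib[, bias_col],
                 predictions = stats::predict(fit$booster, dmat)),
            class = "attribution_matrix")
}

#' @export
print.attribution_matrix <- function(x, ...) {
  cat(sprintf("<attribution_matrix> %d subjects x %d features\n",
              nrow(x$attributions), ncol(x$attributions)))
  invisible(x)
}

#' Aggregate Shapley attributions into percent feature importances
#'
#' Importance of a feature is the mean absolute Shapley attribution over
#' subjects, expressed as a percentage of the sum over all features.
#' (Signed means can cancel to zero, so the absolute value is the reading
#' under which positive percentages are meaningful.)  Features are ordered
#' by descending percentage with alphabetical tie-breaking.
#'
#' @param attributions An `attribution_matrix` from [tree_shap()], or a
#'   plain subjects-by-features matrix.
#' @return An `importance_report` tibble: `feature`, `mean_abs_shap`,
#'   `percent`.
#' @export
aggregate_importance <- function(attributions) {
  m <- if (inherits(attributions, "attribution_matrix")) {
    attributions$attributions
  } else {
    as.matrix(attributions)
  }
  stopifnot(nrow(m) > 0, ncol(m) > 0, !is.null(colnames(m)))
  mean_abs <- unname(colMeans(abs(m)))
  if (sum(mean_abs) == 0) {
    stop("all attributions are zero; importances undefined", call. = FALSE)
  }
  out <- tibble::tibble(feature = colnames(m), mean_abs_shap = mean_abs,
                        percent = 100 * mean_abs / sum(mean_abs))
  out <- out[order(-out$percent, out$feature), ]
  class(out) <- c("importance_report", class(out))
  out
}

#' Feature importances of a selected model
#'
#' Shapley attributions for the model selected by [tune_symptom_model()].
#' By default each fold's model is applied to its own validation fold and
#' the attributions are pooled, mirroring the pooled-prediction philosophy;
#' `refit = "all"` instead refits the selected configuration on the full
#' cohort and attributes every subject under that single model.
#'
#' @param result A `model_result`.
#' @param refit `"pooled"` (default) or `"all"`.
#' @return An `importance_report`; the pooled `attribution_matrix` is
#'   attached as attribute `"attributions"`.
#' @export
model_importance <- function(result, refit = c("pooled", "all")) {
  refit <- match.arg(refit)
  stopifnot(inherits(result, "model_result"))
  if (is.null(result$design)) {
    stop("model result carries no design matrix ",
         "(nested-selection results are not supported here)", call. = FALSE)
  }
  x <- as_feature_matrix(result$design)
  if (refit == "all") {
    fit <- fit_gbdt(x, result$predictions$outcome, result$params)
    am <- tree_shap(fit, x)
  } else {
    folds <- result$cv_fit$folds
    attr_mat <- matrix(NA_real_, nrow(x), ncol(x),
                       dimnames = list(NULL, colnames(x)))
    base <- numeric(nrow(x))
    preds <- numeric(nrow(x))
    for (f in names(result$cv_fit$fits)) {
      hold <- folds == as.integer(f)
      am_f <- tree_shap(result$cv_fit$fits[[f]], x[hold, , drop = FALSE])
      attr_mat[hold, colnames(am_f$attributions)] <- am_f$attributions
      base[hold] <- am_f$base_value
      preds[hold] <- am_f$predictions
    }
    am <- structure(list(attributions = attr_mat, base_value = base,
                         predictions = preds),
                    class = "attribution_matrix")
  }
  rep_out <- aggregate_importance(am)
  attr(rep_out, "attributions") <- am
  rep_out
}

#' Top-k features of an importance report
#'
#' @param report An `importance_report`.
#' @param k Number of features (default 3, as in the per-symptom tables).
#' @return The first `k` rows of the report.
#' @export
top_features <- function(report, k = 3) {
  utils::head(tibble::as_tibble(report), k)
}
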