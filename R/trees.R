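#' Parsed tree structure of a fitted ensemble
#'
#' One row per node across all trees, with original feature names restored.
#' Leaf rows carry the leaf value in `value`; internal rows carry the split
#' feature and threshold (left/`yes` child is taken when the feature value
#' is strictly smaller than the threshold).
#'
#' @param fit A [fit_gbdt()] model.
#' @return A tibble with columns `tree` (1-based), `node_id`, `feature`,
#'   `split`, `yes`, `no`, `missing`, `cover`, `value`.
#' @export
gbdt_trees <- function(fit) {
  stopifnot(inherits(fit, "gbdt_fit"))
  dt <- xgboost::xgb.model.dt.tree(model = fit$booster)
  dt <- tibble::as_tibble(as.data.frame(dt))
  is_leaf <- dt$Feature == "Leaf"
  feat <- ifelse(is_leaf, NA_character_,
                 unname(fit$name_map[dt$Feature]))
  tibble::tibble(
    tree = dt$Tree + 1L,
    node_id = dt$ID,
    feature = feat,
    split = ifelse(is_leaf, NA_real_, dt$Split),
    yes = dt$Yes, no = dt$No, missing = dt$Missing,
    cover = dt$Cover,
    value = ifelse(is_leaf, dt$Gain, NA_real_)
  )
}

bucket_labels <- function() c("high", "medium", "low", "none")

# map a predicted improvement (negative = better) onto the reporting
# buckets: edges are the three ascending interval boundaries
bucket_of <- function(prediction, edges) {
  stopifnot(length(edges) == 3, !is.unsorted(edges))
  bucket_labels()[findInterval(prediction, edges, left.open = TRUE) + 1L]
}

#' Per-patient decision-path explanation
#'
#' Replays one decision tree of a fitted ensemble for a single subject:
#' returns the root-to-leaf path (feature, threshold, and whether the left
#' branch was taken because the value was smaller than the boundary),
#' together with the full-model prediction and its qualitative improvement
#' bucket (`"high"`, `"medium"`, `"low"`, `"none"`, in order of decreasing
#' predicted improvement; the buckets exist for communication only).
#'
#' @param x A `gbdt_fit` or a `model_result`.
#' @param ... Passed to methods.
#' @return A `patient_explanation`: list with `subject_id`, `path` (tibble
#'   of `feature`, `threshold`, `value`, `direction`), `leaf_value`,
#'   `prediction` and `bucket`.
#' @export
explain_patient <- function(x, ...) UseMethod("explain_patient")

#' @rdname explain_patient
#' @param subject_row One-row feature table (original feature names).
#' @param tree Which tree of the ensemble to display (1-based).
#' @param bucket_edges Ascending 3-vector of bucket boundaries on the
#'   predicted improvement scale.
#' @param subject_id Identifier recorded in the explanation.
#' @export
explain_patient.gbdt_fit <- function(x, subject_row, tree = 1,
                                     bucket_edges = c(-2, -1, 0),
                                     subject_id = "subject", ...) {
  row <- as_feature_matrix(subject_row)
  stopifnot(nrow(row) == 1)
  nodes <- gbdt_trees(x)
  nodes <- nodes[nodes$tree == tree, ]
  if (nrow(nodes) == 0) stop("no tree ", tree, " in ensemble", call. = FALSE)
  cur <- nodes$node_id[1]
  steps <- list()
  repeat {
    nd <- nodes[nodes$node_id == cur, ]
    if (is.na(nd$feature)) break
    if (!nd$feature %in% colnames(row)) {
      stop("feature missing from subject row: ", nd$feature, call. = FALSE)
    }
    val <- row[1, nd$feature]
    left <- val < nd$split
    steps[[length(steps) + 1L]] <- tibble::tibble(
      feature = nd$feature, threshold = nd$split, value = val,
      direction = if (left) "left" else "right")
    cur <- if (left) nd$yes else nd$no
  }
  leaf_value <- nodes$value[nodes$node_id == cur]
  prediction <- as.numeric(predict(x, row))
  structure(list(subject_id = subject_id,
                 path = dplyr::bind_rows(steps),
                 leaf_value = leaf_value,
                 prediction = prediction,
                 bucket = bucket_of(prediction, bucket_edges)),
            class = "patient_explanation")
}

#' @rdname explain_patient
#' @export
explain_patient.model_result <- function(x, subject_id, tree = 1,
                                         bucket_edges = NULL, ...) {
  if (is.null(x$design)) {
    stop("model result carries no design matrix", call. = FALSE)
  }
  idx <- match(subject_id, x$predictions$subject_id)
  if (is.na(idx)) stop("unknown subject: ", subject_id, call. = FALSE)
  if (is.null(bucket_edges)) {
    bucket_edges <- unname(stats::quantile(x$predictions$prediction,
                                           c(0.25, 0.5, 0.75)))
  }
  fold <- x$cv_fit$folds[idx]
  fit <- x$cv_fit$fits[[as.character(fold)]]
  out <- explain_patient(fit, x$design[idx, , drop = FALSE], tree = tree,
                         bucket_edges = bucket_edges,
                         subject_id = subject_id)
  out$item <- x$item
  out$symptom <- x$symptom
  out
}

#' @export
print.patient_explanation <- function(x, ...) {
  cat(sprintf("<patient_explanation> %s%s\n", x$subject_id,
              if (!is.null(x$symptom)) paste0(" / ", x$symptom) else ""))
  if (nrow(x$path) > 0) {
    for (i in seq_len(nrow(x$path))) {
      cat(sprintf("  %s = %.4g -> %s (boundary %.4g)\n",
                  x$path$feature[i], x$path$value[i], x$path$direction[i],
                  x$path$threshold[i]))
    }
  }
  cat(sprintf("  prediction %.3f -> %s improvement\n", x$prediction,
              x$bucket))
  invisible(x)
}
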