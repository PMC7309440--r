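#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

# design matrix for one (combination, mode) pair: EEG features from the
# band-power table, baseline HRSD items, optional treatment indicators
build_design <- function(scores, bands, combination, mode,
                         include_treatment) {
  out <- tibble::tibble(subject_id = scores$subject_id)
  if (mode %in% c("eeg_hrsd", "eeg")) {
    stopifnot(!is.null(bands), inherits(combination, "feature_combination"))
    feats <- extract_features(bands, combination)
    feats <- feats[match(scores$subject_id, feats$subject_id), ]
    if (anyNA(feats$subject_id)) {
      stop("band-power table is missing subjects present in the scores",
           call. = FALSE)
    }
    out <- dplyr::bind_cols(out, feats[-1])
  }
  if (mode %in% c("eeg_hrsd", "hrsd")) {
    base <- scores[item_cols("baseline")]
    names(base) <- paste("baseline", hrsd_items()$symptom)
    out <- dplyr::bind_cols(out, base)
  }
  if (include_treatment) {
    if (!"treatment" %in% names(scores) || anyNA(scores$treatment)) {
      stop("treatment arm required for the treatment input mode",
           call. = FALSE)
    }
    for (arm in treatment_arms()) {
      out[[paste("treatment", arm)]] <- as.integer(scores$treatment == arm)
    }
  }
  out
}

grid_params <- function(grid, tree_seed) {
  purrr::pmap(grid[c("n_estimators", "max_depth", "num_leaves",
                     "learning_rate")],
              tree_params, seed = tree_seed)
}

#' Search feature combinations and tree parameters for one symptom
#'
#' The core training procedure: for one HRSD-21 item, every candidate EEG
#' feature combination crossed with every tree-parameter grid point is
#' evaluated by the pooled C index of stratified k-fold out-of-fold
#' predictions of the item's improvement (week 8 minus baseline), and the
#' maximising pair is returned.  Ties are broken by enumeration order
#' (first wins).  In `"eeg_hrsd"` mode the 21 baseline item scores are
#' always appended to the EEG features; `"hrsd"` mode uses the baseline
#' scores alone (the feature-combination axis collapses);
#' `include_treatment` adds three binary treatment-arm indicators.
#'
#' @param cohort A `cohort_dataset` from [apply_exclusions()], or a wide
#'   score table with complete week-8 visits.
#' @param bands Band-power table from [band_power_table()] (not needed in
#'   `"hrsd"` mode).
#' @param item HRSD item number (1-21).
#' @param mode Input mode: `"eeg_hrsd"` (default), `"hrsd"`, or `"eeg"`.
#' @param combos List of [feature_combination()]s in search order; default
#'   the full enumeration of [enumerate_feature_combinations()].
#' @param grid Hyperparameter grid from [param_grid()].
#' @param cv A [cv_config()].
#' @param cfg An [eval_config()] for the bootstrap CI of the selected model.
#' @param include_treatment Add treatment-arm indicator features.
#' @param tree_seed Seed handed to every tree fit.
#' @param nested Select hyperparameters inside each training fold by an
#'   inner pooled CV instead of on the reported (outer) pooled CV.  The
#'   default mirrors the single-level pooled procedure; the optimism this
#'   induces is discussed in the methods vignette.
#' @return A `model_result`; see [tidy.model_result()] and
#'   [glance.model_result()].
#' @export
tune_symptom_model <- function(cohort, bands = NULL, item,
                               mode = c("eeg_hrsd", "hrsd", "eeg"),
                               combos = NULL, grid = param_grid(),
                               cv = cv_config(), cfg = eval_config(),
                               include_treatment = FALSE, tree_seed = 0L,
                               nested = FALSE) {
  mode <- match.arg(mode)
  scores <- if (inherits(cohort, "cohort_dataset")) cohort$subjects
            else tibble::as_tibble(cohort)
  stopifnot(nrow(scores) >= cv$k, item %in% 1:21, nrow(grid) >= 1)
  imp <- compute_improvement(scores)
  outcomes <- imp$improvement[imp$item == item]
  if (length(unique(outcomes)) < 2) {
    stop("all pairs degenerate: improvement on item ", item,
         " is constant", call. = FALSE)
  }
  if (mode == "hrsd") {
    combos <- list(NULL)
  } else if (is.null(combos)) {
    combos <- enumerate_feature_combinations()
  }
  stopifnot(length(combos) >= 1)
  params_list <- grid_params(grid, tree_seed)
  folds <- stratified_folds(outcomes, cv)

  if (nested) {
    return(nested_search(scores, bands, item, mode, combos, grid,
                         params_list, cv, cfg, include_treatment,
                         outcomes, folds))
  }

  best <- NULL
  log_rows <- list()
  for (ci_combo in seq_along(combos)) {
    design <- build_design(scores, bands, combos[[ci_combo]], mode,
                           include_treatment)
    for (gi in seq_along(params_list)) {
      cvfit <- pooled_cv_predict(design, outcomes, params_list[[gi]], folds)
      score <- c_index(cvfit$predictions, outcomes)
      log_rows[[length(log_rows) + 1L]] <- tibble::tibble(
        combination = if (is.null(combos[[ci_combo]])) "baseline HRSD"
                      else format(combos[[ci_combo]]),
        n_estimators = params_list[[gi]]$n_estimators,
        max_depth = params_list[[gi]]$max_depth,
        num_leaves = params_list[[gi]]$num_leaves,
        c_index = score)
      if (is.null(best) || score > best$score) {
        best <- list(score = score, combo = combos[[ci_combo]],
                     params = params_list[[gi]], cvfit = cvfit,
                     design = design)
      }
    }
  }
  ci <- bootstrap_ci(best$cvfit$predictions, outcomes, cfg)
  new_model_result(item, mode, include_treatment, best$combo, best$params,
                  scores$subject_id, outcomes, best$cvfit, best$score,
                  ci, dplyr::bind_rows(log_rows), best$design)
}

nested_search <- function(scores, bands, item, mode, combos, grid,
                          params_list, cv, cfg, include_treatment,
                          outcomes, folds) {
  designs <- purrr::map(combos, build_design, scores = scores,
                        bands = bands, mode = mode,
                        include_treatment = include_treatment)
  preds <- rep(NA_real_, length(outcomes))
  chosen <- character(0)
  fits <- list()
  for (f in sort(unique(folds))) {
    hold <- folds == f
    inner_cv <- cv_config(cv$k, cv$seed + f)
    inner_folds <- stratified_folds(outcomes[!hold], inner_cv)
    inner_best <- NULL
    for (ci_combo in seq_along(designs)) {
      train <- designs[[ci_combo]][!hold, , drop = FALSE]
      for (gi in seq_along(params_list)) {
        cvfit <- pooled_cv_predict(train, outcomes[!hold],
                                   params_list[[gi]], inner_folds)
        score <- c_index(cvfit$predictions, outcomes[!hold])
        if (is.null(inner_best) || score > inner_best$score) {
          inner_best <- list(score = score, ci_combo = ci_combo, gi = gi)
        }
      }
    }
    fit <- fit_gbdt(designs[[inner_best$ci_combo]][!hold, , drop = FALSE],
                    outcomes[!hold], params_list[[inner_best$gi]])
    preds[hold] <- predict(
      fit, designs[[inner_best$ci_combo]][hold, , drop = FALSE])
    fits[[as.character(f)]] <- fit
    chosen[f] <- paste0(
      if (is.null(combos[[inner_best$ci_combo]])) "baseline HRSD"
      else format(combos[[inner_best$ci_combo]]),
      " / grid ", inner_best$gi)
  }
  modal <- names(sort(table(chosen), decreasing = TRUE))[1]
  score <- c_index(preds, outcomes)
  ci <- bootstrap_ci(preds, outcomes, cfg)
  cvfit <- structure(list(predictions = preds, fits = fits, folds = folds),
                     class = "cv_fit")
  res <- new_model_result(item, mode, include_treatment, NULL,
                          params_list[[1]], scores$subject_id, outcomes,
                          cvfit, score, ci,
                          tibble::tibble(combination = chosen,
                                         n_estimators = NA_integer_,
                                         max_depth = NA_integer_,
                                         num_leaves = NA_integer_,
                                         c_index = NA_real_), NULL)
  res$nested <- TRUE
  res$modal_choice <- modal
  res
}

new_model_result <- function(item, mode, include_treatment, combo, params,
                             subject_ids, outcomes, cvfit, score, ci,
                             search_log, design = NULL) {
  structure(list(
    item = item,
    symptom = hrsd_items()$symptom[item],
    input_mode = paste0(mode, if (include_treatment) "+treatment"),
    combination = combo,
    params = params,
    predictions = tibble::tibble(subject_id = subject_ids,
                                 outcome = outcomes,
                                 prediction = cvfit$predictions),
    cv_fit = cvfit,
    c_index = score,
    ci_low = ci$low,
    ci_high = ci$high,
    search = search_log,
    design = design,
    n = length(outcomes)),
    class = "model_result")
}

#' @export
print.model_result <- function(x, ...) {
  cat(sprintf("<model_result> item %d (%s), mode %s\n", x$item, x$symptom,
              x$input_mode))
  if (!is.null(x$combination)) {
    cat("  combination: ", format(x$combination), "\n", sep = "")
  }
  cat(sprintf("  C index %.3f (95%% CI %.3f-%.3f), n = %d\n",
              x$c_index, x$ci_low, x$ci_high, x$n))
  invisible(x)
}

#' Tidy a model result into per-subject predictions
#'
#' @param x A `model_result`.
#' @param ... Unused.
#' @return Tibble of `subject_id`, `outcome`, `prediction`, `fold`.
#' @export
tidy.model_result <- function(x, ...) {
  dplyr::mutate(x$predictions, fold = x$cv_fit$folds)
}

#' One-row summary of a model result
#'
#' @param x A `model_result`.
#' @param ... Unused.
#' @return A one-row tibble with the item, symptom, input mode, selected
#'   combination and parameters, pooled C index and its bootstrap CI.
#' @export
glance.model_result <- function(x, ...) {
  tibble::tibble(
    item = x$item, symptom = x$symptom, input_mode = x$input_mode,
    combination = if (is.null(x$combination)) NA_character_
                  else format(x$combination),
    n_estimators = x$params$n_estimators, max_depth = x$params$max_depth,
    num_leaves = x$params$num_leaves,
    c_index = x$c_index, ci_low = x$ci_low, ci_high = x$ci_high, n = x$n)
}
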