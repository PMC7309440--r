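#' Run the full analysis pipeline from a configuration
#'
#' Orchestrates simulate (or load) -> band-power extraction -> per-symptom
#' model search (per input mode) -> evaluation (pooled C index with
#' bootstrap CI, calibrated fit metrics, paired C-index differences against
#' the baseline-scores-only model) -> Shapley importances -> report.  All
#' randomness derives from the mandatory `seed`; rerunning with an identical
#' configuration reproduces byte-identical JSON reports.
#'
#' The configuration is a named list (or a YAML file path) with entries:
#' \describe{
#'   \item{seed}{integer, mandatory.}
#'   \item{simulation}{optional list passed to [sim_config()] (`n_subjects`,
#'     `duration`, ..., and optionally `planted_item`, `planted_feature`,
#'     `beta2`, `sigma` for [default_effects()]).}
#'   \item{paths}{alternative to `simulation`: list with `scores` (CSV) and
#'     `eeg_dir` (directory of `<subject_id>.csv` recordings).}
#'   \item{items}{HRSD items to model (default all 21).}
#'   \item{modes}{input modes, subset of `c("eeg_hrsd", "hrsd", "eeg")`
#'     (default `c("eeg_hrsd", "hrsd")`).}
#'   \item{include_treatment}{logical (default `FALSE`).}
#'   \item{search}{arguments for [enumerate_feature_combinations()].}
#'   \item{grid}{arguments for [param_grid()].}
#'   \item{cv, eval}{arguments for [cv_config()] / [eval_config()] (seeds
#'     are derived from the global seed).}
#'   \item{window_seconds}{Welch window (default 2).}
#'   \item{bucket_edges}{explanation bucket boundaries (default quartiles of
#'     the predicted improvements).}
#' }
#'
#' @param config Named list or path to a YAML file.
#' @param output_dir Directory to write reports into (created if needed).
#' @return Invisibly, a list with `results` (tibble of per-item, per-mode
#'   summaries), `deltas`, `importance`, `explanation`, and `output_dir`.
#' @export
run_pipeline <- function(config, output_dir) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  if (is.null(config$seed)) stop("config error: seed is mandatory",
                                 call. = FALSE)
  has_sim <- !is.null(config$simulation)
  if (!has_sim) {
    if (is.null(config$paths$scores) || !file.exists(config$paths$scores)) {
      stop("config error: missing scores path and no simulation block",
           call. = FALSE)
    }
  }
  seed <- as.integer(config$seed)
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  t0 <- proc.time()[["elapsed"]]
  stage <- function(msg) {
    message(sprintf("[%7.1fs] %s", proc.time()[["elapsed"]] - t0, msg))
  }
  window_seconds <- config$window_seconds %||% 2

  stage("stage data: loading or simulating cohort")
  if (has_sim) {
    sb <- config$simulation
    eff_args <- sb[intersect(names(sb), c("planted_item", "planted_feature",
                                          "beta2", "sigma"))]
    effects <- do.call(default_effects, eff_args)
    sc_args <- sb[intersect(names(sb),
                            c("n_subjects", "sampling_rate", "duration",
                              "baseline_mean_frac", "baseline_sd_frac",
                              "subject_sd"))]
    scfg <- do.call(sim_config, c(sc_args, list(effects = effects,
                                                seed = seed)))
    sim <- simulate_cohort(scfg, keep_recordings = FALSE,
                           window_seconds = window_seconds)
    scores <- sim$scores
    bands <- sim$bands
    truth <- sim$truth
  } else {
    scores <- read_scores(config$paths$scores)
    files <- file.path(config$paths$eeg_dir,
                       paste0(scores$subject_id, ".csv"))
    present <- file.exists(files)
    scores$eeg_present <- present
    recs <- purrr::map(files[present], read_eeg_csv)
    names(recs) <- scores$subject_id[present]
    bands <- band_power_table(recs, window_seconds = window_seconds)
    truth <- NULL
  }

  stage("stage cohort: applying exclusions")
  cohort <- apply_exclusions(scores)
  bands <- bands[bands$subject_id %in% cohort$subjects$subject_id, ]

  items <- as.integer(config$items %||% 1:21)
  modes <- config$modes %||% c("eeg_hrsd", "hrsd")
  include_treatment <- isTRUE(config$include_treatment)
  combos <- do.call(enumerate_feature_combinations, config$search %||% list())
  grid <- do.call(param_grid, config$grid %||% list())
  k <- (config$cv$k %||% 5)
  B <- (config$eval$B %||% 1000)
  ci_level <- (config$eval$ci_level %||% 0.95)

  results <- list()
  models <- list()
  deltas <- list()
  importance <- list()
  for (item in items) {
    for (mode in modes) {
      stage(sprintf("stage search: item %d, mode %s", item, mode))
      res <- tune_symptom_model(
        cohort, bands = bands, item = item, mode = mode,
        combos = combos, grid = grid,
        cv = cv_config(k, seed + item),
        cfg = eval_config(B, ci_level, seed + item),
        include_treatment = include_treatment, tree_seed = seed)
      models[[paste(item, mode)]] <- res
      cal <- calibrate(res$predictions$prediction, res$predictions$outcome)
      fm <- fit_metrics(cal, res$predictions$prediction,
                        res$predictions$outcome)
      results[[paste(item, mode)]] <-
        dplyr::bind_cols(glance(res), fm[c("r_squared", "mae")],
                         tibble::tibble(cal_slope = fm$slope,
                                        cal_intercept = fm$intercept))
      readr::write_csv(tidy(res),
                       file.path(output_dir,
                                 sprintf("predictions_item%02d_%s.csv",
                                         item, mode)),
                       progress = FALSE)
    }
    if (all(c("eeg_hrsd", "hrsd") %in% modes)) {
      stage(sprintf("stage evaluate: item %d paired C-index difference",
                    item))
      a <- models[[paste(item, "eeg_hrsd")]]
      b <- models[[paste(item, "hrsd")]]
      dc <- delta_c_index(a$predictions$prediction,
                          b$predictions$prediction,
                          a$predictions$outcome,
                          eval_config(B, ci_level, seed + item))
      deltas[[as.character(item)]] <-
        dplyr::bind_cols(tibble::tibble(item = item,
                                        symptom = a$symptom), dc)
    }
    imp_mode <- if ("eeg_hrsd" %in% modes) "eeg_hrsd" else modes[1]
    imp <- model_importance(models[[paste(item, imp_mode)]])
    importance[[as.character(item)]] <- dplyr::bind_cols(
      tibble::tibble(item = item), top_features(imp, 3))
  }

  stage("stage report: explanation and serialisation")
  first <- models[[paste(items[1], if ("eeg_hrsd" %in% modes) "eeg_hrsd"
                                   else modes[1])]]
  expl <- explain_patient(first, first$predictions$subject_id[1],
                          bucket_edges = config$bucket_edges)
  out <- list(
    results = dplyr::bind_rows(results),
    deltas = dplyr::bind_rows(deltas),
    importance = dplyr::bind_rows(importance),
    truth = truth,
    explanation = expl,
    output_dir = output_dir)

  report <- list(
    seed = seed,
    n_retained = nrow(cohort$subjects),
    provenance = provenance(cohort),
    results = out$results,
    delta_c = out$deltas,
    importance_top3 = out$importance,
    planted_truth = truth,
    explanation = list(subject_id = expl$subject_id, item = expl$item,
                       path = expl$path, prediction = expl$prediction,
                       bucket = expl$bucket))
  jsonlite::write_json(report, file.path(output_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  jsonlite::write_json(provenance(cohort),
                       file.path(output_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  files <- sort(setdiff(list.files(output_dir), "manifest.json"))
  manifest <- list(
    package = "eegboost",
    version = as.character(utils::packageVersion("eegboost")),
    seed = seed,
    config = config,
    hashes = as.list(tools::md5sum(file.path(output_dir, files))))
  names(manifest$hashes) <- files
  jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  stage("done")
  invisible(out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
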