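#' HRSD-21 item catalogue
#'
#' The 21 items of the Hamilton Rating Scale for Depression with their rating
#' scales: ten items are rated 0-4 (absent to very severe) and eleven items
#' are rated 0-2 (absent, doubtful or mild, clearly present).
#'
#' @return A tibble with columns `item` (1-21), `symptom` (short descriptor)
#'   and `scale_max` (4 or 2).
#' @export
#' @examples
#' hrsd_items()
hrsd_items <- function() {
  tibble::tibble(
    item = 1:21,
    symptom = c(
      "depressed mood", "self-critical", "suicidal thoughts",
      "trouble sleeping", "nighttime awakening", "waking early",
      "loss of interest", "psychomotor retardation", "agitation",
      "worrying", "physical anxiety", "appetite changes", "energy loss",
      "libido loss", "health preoccupation", "weight loss",
      "loss of insight", "diurnal variation", "unreality and nihilism",
      "paranoia", "obsessive thoughts"
    ),
    scale_max = ifelse(1:21 %in% c(1, 2, 3, 7, 8, 9, 10, 11, 15, 19), 4L, 2L)
  )
}

treatment_arms <- function() c("escitalopram", "sertraline", "venlafaxine_xr")

item_cols <- function(visit) sprintf("%s_%02d", visit, 1:21)

#' Validate a wide HRSD-21 score table
#'
#' Checks the documented wide layout: one row per subject, columns
#' `subject_id`, `baseline_01` ... `baseline_21`, `week8_01` ... `week8_21`,
#' and optionally `treatment`, `eeg_present`, `features_complete`.  Scores
#' must be integers within each item's scale (0-4 for the ten 5-point items,
#' 0-2 for the eleven 3-point items); week-8 scores may be missing (dropout).
#' Violations are reported with the offending rows.
#'
#' @param scores A data frame in the wide score layout.
#' @return `scores` invisibly, as a tibble, if valid; otherwise an error.
#' @export
validate_scores <- function(scores) {
  scores <- tibble::as_tibble(scores)
  needed <- c("subject_id", item_cols("baseline"), item_cols("week8"))
  missing_cols <- setdiff(needed, names(scores))
  if (length(missing_cols) > 0) {
    stop("malformed score table; missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  dup <- scores$subject_id[duplicated(scores$subject_id)]
  if (length(dup) > 0) {
    stop("duplicated subject_id(s): ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  if ("treatment" %in% names(scores)) {
    bad_arm <- !is.na(scores$treatment) &
      !scores$treatment %in% treatment_arms()
    if (any(bad_arm)) {
      stop("invalid treatment arm in row(s) ",
           paste(which(bad_arm), collapse = ", "),
           "; expected one of ", paste(treatment_arms(), collapse = ", "),
           call. = FALSE)
    }
  }
  scale_max <- hrsd_items()$scale_max
  for (visit in c("baseline", "week8")) {
    vals <- as.matrix(scores[item_cols(visit)])
    if (visit == "baseline" && anyNA(vals)) {
      stop("missing baseline score(s) in row(s) ",
           paste(which(rowSums(is.na(vals)) > 0), collapse = ", "),
           call. = FALSE)
    }
    not_int <- !is.na(vals) & vals != round(vals)
    out_of_range <- sweep(vals, 2, scale_max, ">") | vals < 0
    bad <- not_int | (!is.na(out_of_range) & out_of_range)
    if (any(bad, na.rm = TRUE)) {
      idx <- which(bad, arr.ind = TRUE)
      msg <- sprintf("row %d, %s item %d: score %s outside 0-%d",
                     idx[, 1], visit, idx[, 2],
                     format(vals[idx]), scale_max[idx[, 2]])
      stop("out-of-range score(s):\n  ",
           paste(utils::head(msg, 10), collapse = "\n  "), call. = FALSE)
    }
  }
  invisible(scores)
}

#' Per-item symptom improvement (week 8 minus baseline)
#'
#' Improvement for each HRSD-21 item is the week-8 score minus the baseline
#' score; negative values indicate symptom improvement.  Every subject must
#' have a complete week-8 visit: a visit with any missing item is treated as
#' a dropout and rejected (apply [apply_exclusions()] first).
#'
#' @param scores A validated wide score table (see [validate_scores()]).
#' @return A long tibble with columns `subject_id`, `item`, `symptom`,
#'   `baseline`, `week8`, `improvement`.
#' @export
#' @examples
#' scores <- tibble::tibble(subject_id = "s1")
#' scores[sprintf("baseline_%02d", 1:21)] <- as.list(rep(2L, 21))
#' scores[sprintf("week8_%02d", 1:21)] <- as.list(rep(1L, 21))
#' compute_improvement(scores)
compute_improvement <- function(scores) {
  scores <- validate_scores(scores)
  week8 <- as.matrix(scores[item_cols("week8")])
  dropouts <- rowSums(is.na(week8)) > 0
  if (any(dropouts)) {
    stop("dropout: missing week-8 score(s) for subject(s) ",
         paste(scores$subject_id[dropouts], collapse = ", "), call. = FALSE)
  }
  long <- tidyr::pivot_longer(
    scores[c("subject_id", item_cols("baseline"), item_cols("week8"))],
    cols = -"subject_id",
    names_to = c("visit", "item"), names_sep = "_(?=[0-9]+$)",
    values_to = "score"
  )
  long$item <- as.integer(long$item)
  wide <- tidyr::pivot_wider(long, names_from = "visit",
                             values_from = "score")
  out <- dplyr::mutate(
    dplyr::left_join(wide, hrsd_items()[c("item", "symptom")], by = "item"),
    improvement = .data$week8 - .data$baseline
  )
  out[c("subject_id", "item", "symptom", "baseline", "week8", "improvement")]
}

#' Apply the cohort exclusion flow
#'
#' Excludes, in order: (1) dropouts (subjects with any missing week-8 item),
#' (2) subjects with missing EEG (`eeg_present` is `FALSE`), (3) subjects
#' with incomplete features (`features_complete` is `FALSE`).  Each step's
#' count is measured among the subjects surviving the previous steps, and
#' the full flow is recorded in the returned provenance table.  Missing
#' `eeg_present` / `features_complete` columns are treated as all-present.
#'
#' @param roster A wide score table, optionally with logical columns
#'   `eeg_present` and `features_complete`.
#' @return A `cohort_dataset`: list with `subjects` (the retained rows) and
#'   `provenance` (tibble of steps, exclusion counts and remaining counts).
#' @export
apply_exclusions <- function(roster) {
  roster <- tibble::as_tibble(roster)
  if (nrow(roster) > 0) validate_scores(roster)
  keep <- roster
  steps <- tibble::tibble(step = character(), excluded = integer(),
                          remaining = integer())
  flag_of <- function(df, what) {
    switch(what,
      dropout = if (nrow(df) == 0) logical(0) else
        rowSums(is.na(as.matrix(df[item_cols("week8")]))) > 0,
      missing_eeg = if (!"eeg_present" %in% names(df))
        rep(FALSE, nrow(df)) else !df$eeg_present,
      missing_features = if (!"features_complete" %in% names(df))
        rep(FALSE, nrow(df)) else !df$features_complete
    )
  }
  for (what in c("dropout", "missing_eeg", "missing_features")) {
    drop <- flag_of(keep, what)
    keep <- keep[!drop, , drop = FALSE]
    steps <- dplyr::bind_rows(steps, tibble::tibble(
      step = what, excluded = sum(drop), remaining = nrow(keep)))
  }
  structure(
    list(subjects = keep,
         provenance = dplyr::bind_rows(
           tibble::tibble(step = "enrolled", excluded = 0L,
                          remaining = nrow(roster)),
           steps)),
    class = "cohort_dataset")
}

#' @export
print.cohort_dataset <- function(x, ...) {
  cat("<cohort_dataset> ", nrow(x$subjects), " subjects retained\n", sep = "")
  print(x$provenance)
  invisible(x)
}

#' @rdname apply_exclusions
#' @param cohort A `cohort_dataset`.
#' @export
provenance <- function(cohort) {
  stopifnot(inherits(cohort, "cohort_dataset"))
  cohort$provenance
}

#' Read and write HRSD-21 score tables
#'
#' Lossless round-trip of the documented CSV dialect: UTF-8,
#' comma-separated, header row, one row per subject with wide visit columns
#' (`baseline_01..21`, `week8_01..21`), optional `treatment`,
#' `eeg_present`, `features_complete`.  Reading validates scales and
#' subject-id uniqueness with row-level diagnostics.
#'
#' @param path CSV file path.
#' @return `read_scores()` returns the validated tibble; `write_scores()`
#'   returns `path` invisibly.
#' @export
read_scores <- function(path) {
  scores <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  for (col in intersect(c(item_cols("baseline"), item_cols("week8")),
                        names(scores))) {
    scores[[col]] <- as.integer(scores[[col]])
  }
  validate_scores(scores)
  tibble::as_tibble(scores)
}

#' @rdname read_scores
#' @param scores A wide score table.
#' @export
write_scores <- function(scores, path) {
  validate_scores(scores)
  readr::write_csv(scores, path, progress = FALSE)
  invisible(path)
}
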