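#' Evaluation configuration
#'
#' @param B Number of bootstrap replicates (default 1000).
#' @param ci_level Confidence level for percentile intervals (default 0.95).
#' @param seed Seed for the bootstrap resampling.
#' @return An `eval_config` object.
#' @export
eval_config <- function(B = 1000, ci_level = 0.95, seed = 7L) {
  stopifnot(B >= 1, ci_level > 0, ci_level < 1)
  structure(list(B = as.integer(B), ci_level = ci_level,
                 seed = as.integer(seed)),
            class = "eval_config")
}

#' Concordance index for continuous predictions
#'
#' The proportion of usable subject pairs (pairs with unequal outcomes) in
#' which predictions and outcomes are concordant, i.e. the probability that
#' the model correctly ranks two subjects with different outcomes.  Tied
#' predictions on a usable pair contribute half credit, so constant
#' predictions score exactly 0.5.
#'
#' @param predictions,outcomes Equal-length numeric vectors.
#' @return A value in `[0, 1]`.
#' @export
#' @examples
#' c_index(c(1, 2, 3), c(1, 2, 3))  # 1
#' c_index(c(3, 2, 1), c(1, 2, 3))  # 0
c_index <- function(predictions, outcomes) {
  stopifnot(is.numeric(predictions), is.numeric(outcomes),
            length(predictions) == length(outcomes))
  if (anyNA(predictions) || anyNA(outcomes)) {
    stop("missing values in predictions or outcomes", call. = FALSE)
  }
  if (length(unique(outcomes)) < 2) {
    stop("C index undefined: all outcomes equal", call. = FALSE)
  }
  .cindex_pairs(as.numeric(predictions), as.numeric(outcomes))
}

#' Bootstrap confidence interval for a pooled metric
#'
#' Nonparametric bootstrap over paired (prediction, outcome) resamples of
#' the pooled cohort, with percentile intervals by default and
#' bias-corrected accelerated (BCa) intervals behind a flag.  Resamples on
#' which the metric is undefined (for the C index: a resample with constant
#' outcomes) are skipped and counted; more than 50% degenerate resamples is
#' an error.  Deterministic given the seed.
#'
#' @param predictions,outcomes Equal-length numeric vectors.
#' @param cfg An [eval_config()].
#' @param metric Function `(predictions, outcomes) -> scalar`
#'   (default [c_index()]).
#' @param type `"percentile"` (default) or `"bca"` (adds a jackknife pass
#'   for the acceleration constant).
#' @return A one-row tibble: `estimate`, `low`, `high`, `b_used`.
#' @export
bootstrap_ci <- function(predictions, outcomes, cfg = eval_config(),
                         metric = c_index,
                         type = c("percentile", "bca")) {
  type <- match.arg(type)
  stopifnot(inherits(cfg, "eval_config"),
            length(predictions) == length(outcomes))
  n <- length(outcomes)
  estimate <- metric(predictions, outcomes)
  vals <- with_seed(cfg$seed, {
    vapply(seq_len(cfg$B), function(b) {
      idx <- sample.int(n, n, replace = TRUE)
      tryCatch(metric(predictions[idx], outcomes[idx]),
               error = function(e) NA_real_)
    }, numeric(1))
  })
  ok <- !is.na(vals)
  if (sum(!ok) > cfg$B / 2) {
    stop("more than half of the bootstrap resamples were degenerate",
         call. = FALSE)
  }
  alpha <- (1 - cfg$ci_level) / 2
  probs <- c(alpha, 1 - alpha)
  if (type == "bca") {
    z0 <- stats::qnorm(mean(vals[ok] < estimate) +
                         0.5 * mean(vals[ok] == estimate))
    jack <- vapply(seq_len(n), function(i) {
      tryCatch(metric(predictions[-i], outcomes[-i]),
               error = function(e) NA_real_)
    }, numeric(1))
    jack <- jack[!is.na(jack)]
    d <- mean(jack) - jack
    a <- sum(d^3) / (6 * sum(d^2)^1.5)
    if (is.finite(z0) && is.finite(a)) {
      zq <- stats::qnorm(probs)
      probs <- stats::pnorm(z0 + (z0 + zq) / (1 - a * (z0 + zq)))
    }
  }
  q <- stats::quantile(vals[ok], probs, names = FALSE)
  tibble::tibble(estimate = estimate, low = q[1], high = q[2],
                 b_used = sum(ok))
}

#' Fit the univariate lasso calibration map
#'
#' Linear map from raw model predictions to outcomes, fitted by minimising
#' `1/(2n) * sum((y - b0 - b1 x)^2) + lambda * |b1|` (the lasso objective in
#' its standard per-observation scaling), which for a single predictor has
#' the closed-form soft-thresholding solution.
#'
#' @param predictions,outcomes Training predictions and observed outcomes.
#' @param lambda Regularisation coefficient (default 0.01).
#' @return A `calibration_model` with `slope`, `intercept`, `lambda`.
#' @export
calibrate <- function(predictions, outcomes, lambda = 0.01) {
  stopifnot(length(predictions) == length(outcomes),
            length(outcomes) >= 2, lambda >= 0)
  xm <- mean(predictions)
  ym <- mean(outcomes)
  sxx <- mean((predictions - xm)^2)
  if (sxx <= 0) stop("constant predictions", call. = FALSE)
  sxy <- mean((predictions - xm) * (outcomes - ym))
  slope <- sign(sxy) * max(abs(sxy) - lambda, 0) / sxx
  structure(list(slope = slope, intercept = ym - slope * xm,
                 lambda = lambda),
            class = "calibration_model")
}

#' @export
print.calibration_model <- function(x, ...) {
  cat(sprintf("<calibration_model> y = %.4f + %.4f x (lambda = %g)\n",
              x$intercept, x$slope, x$lambda))
  invisible(x)
}

#' @export
predict.calibration_model <- function(object, newdata, ...) {
  object$intercept + object$slope * as.numeric(newdata)
}

#' Goodness-of-fit metrics after calibration
#'
#' Applies the calibration map to the raw predictions, then reports the
#' coefficient of determination `R^2 = 1 - SS_res / SS_tot`, the mean
#' absolute error, and the calibration slope and intercept.
#'
#' @param calibration A [calibrate()] model.
#' @param predictions,outcomes Raw predictions and observed outcomes.
#' @return A one-row tibble: `r_squared`, `mae`, `slope`, `intercept`.
#' @export
fit_metrics <- function(calibration, predictions, outcomes) {
  stopifnot(inherits(calibration, "calibration_model"),
            length(predictions) == length(outcomes))
  ss_tot <- sum((outcomes - mean(outcomes))^2)
  if (ss_tot <= 0) stop("zero outcome variance", call. = FALSE)
  yhat <- predict(calibration, predictions)
  tibble::tibble(
    r_squared = 1 - sum((outcomes - yhat)^2) / ss_tot,
    mae = mean(abs(outcomes - yhat)),
    slope = calibration$slope,
    intercept = calibration$intercept
  )
}

#' Paired C-index difference with bootstrap confidence interval
#'
#' Difference in C index between two models evaluated on the same subjects
#' (e.g. EEG + baseline symptoms vs baseline symptoms alone), with a paired
#' bootstrap: each resample of subjects is applied to both prediction
#' vectors, so the interval reflects the correlated uncertainty.  The
#' difference is called significant when the interval excludes zero.
#'
#' @param preds_a,preds_b Prediction vectors aligned to the same subjects.
#' @param outcomes Observed outcomes.
#' @param cfg An [eval_config()].
#' @return A one-row tibble: `delta_c`, `low`, `high`, `significant`.
#' @export
delta_c_index <- function(preds_a, preds_b, outcomes, cfg = eval_config()) {
  stopifnot(inherits(cfg, "eval_config"),
            length(preds_a) == length(outcomes),
            length(preds_b) == length(outcomes))
  delta <- c_index(preds_a, outcomes) - c_index(preds_b, outcomes)
  n <- length(outcomes)
  vals <- with_seed(cfg$seed, {
    vapply(seq_len(cfg$B), function(b) {
      idx <- sample.int(n, n, replace = TRUE)
      if (length(unique(outcomes[idx])) < 2) return(NA_real_)
      .cindex_pairs(preds_a[idx], outcomes[idx]) -
        .cindex_pairs(preds_b[idx], outcomes[idx])
    }, numeric(1))
  })
  ok <- !is.na(vals)
  if (sum(!ok) > cfg$B / 2) {
    stop("more than half of the bootstrap resamples were degenerate",
         call. = FALSE)
  }
  alpha <- (1 - cfg$ci_level) / 2
  q <- stats::quantile(vals[ok], c(alpha, 1 - alpha), names = FALSE)
  tibble::tibble(delta_c = delta, low = q[1], high = q[2],
                 significant = q[1] > 0 | q[2] < 0)
}
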