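#' Default per-site band amplitude profile
#'
#' Root-mean-square amplitude (microvolts) of each canonical band at each
#' montage site for the synthetic eyes-closed resting EEG.  The profile has
#' the qualitative topography the analysis relies on: a posterior-dominant
#' alpha rhythm (boosted over occipital and parietal sites), strong slow
#' (delta/theta) activity and weak fast (beta/gamma) activity.
#'
#' @return Numeric matrix, 26 sites x 5 bands, with dimnames.
#' @export
default_amplitude_profile <- function() {
  montage <- eeg_montage()
  amp <- matrix(rep(c(delta = 18, theta = 9, alpha = 12, beta = 5,
                      gamma = 2.5), each = nrow(montage)),
                nrow = nrow(montage),
                dimnames = list(montage$site, eeg_bands()$band))
  amp[montage$region == "occipital", "alpha"] <-
    amp[montage$region == "occipital", "alpha"] * 1.8
  amp[montage$region == "parietal", "alpha"] <-
    amp[montage$region == "parietal", "alpha"] * 1.4
  amp[montage$region == "frontal", "delta"] <-
    amp[montage$region == "frontal", "delta"] * 1.2
  amp
}

check_profile <- function(profile) {
  stopifnot(is.matrix(profile), is.numeric(profile),
            !is.null(rownames(profile)), !is.null(colnames(profile)))
  if (any(profile < 0)) stop("band amplitudes must be >= 0", call. = FALSE)
  if (!all(colnames(profile) %in% eeg_bands()$band)) {
    stop("profile columns must be canonical band names", call. = FALSE)
  }
  invisible(resolve_site(rownames(profile)))
}

#' Simulate one band-structured EEG recording
#'
#' Each channel is a sum over bands of band-limited Gaussian noise,
#' synthesised in the frequency domain (independent complex-Gaussian Fourier
#' coefficients confined to each band, inverse transformed), so the expected
#' band power equals the squared band amplitude.  Bands extending beyond the
#' Nyquist frequency are truncated to the representable edge with a message.
#'
#' @param profile Site-by-band amplitude matrix (microvolts RMS), e.g.
#'   [default_amplitude_profile()], possibly scaled per subject.
#' @param sampling_rate Sampling rate in Hz (default 250).
#' @param duration Recording length in seconds (default 120, the eyes-closed
#'   resting protocol).
#' @param seed Optional integer seed; when given the recording is a pure
#'   function of `(profile, sampling_rate, duration, seed)`.
#' @return An [eeg_recording()].
#' @export
simulate_recording <- function(profile, sampling_rate = 250,
                               duration = 120, seed = NULL) {
  sites <- check_profile(profile)
  stopifnot(sampling_rate > 0, duration > 0)
  if (!is.null(seed)) set.seed(seed)
  n <- round(duration * sampling_rate)
  nyq <- sampling_rate / 2
  bands <- eeg_bands()
  freq <- (1:(ceiling(n / 2) - 1)) * sampling_rate / n  # positive-freq bins
  active <- colnames(profile)[colSums(profile) > 0]
  if (length(active) > 0 &&
      max(bands$f_lo[bands$band %in% active]) >= nyq) {
    stop("sampling rate ", sampling_rate,
         " Hz is below Nyquist for the requested bands", call. = FALSE)
  }
  bins <- lapply(seq_len(nrow(bands)), function(b) {
    hi <- min(bands$f_hi[b], nyq)
    if (hi < bands$f_hi[b] && bands$band[b] %in% active) {
      message("band ", bands$band[b], " truncated at ", hi,
              " Hz (Nyquist-safe edge)")
    }
    which(freq > bands$f_lo[b] & freq <= hi)
  })
  names(bins) <- bands$band
  all_idx <- unlist(bins[colnames(profile)], use.names = FALSE)
  m_tot <- length(all_idx)
  nch <- length(sites)
  # per-bin amplitude scale so each realised band variance has
  # expectation amplitude^2
  scale_rows <- do.call(rbind, lapply(colnames(profile), function(bn) {
    m <- length(bins[[bn]])
    if (m == 0) return(NULL)
    matrix(rep(profile[, bn] * n / (2 * sqrt(m)), each = m), m, nch)
  }))
  spec <- matrix(complex(real = 0), n, nch)
  coefs <- matrix(complex(real = stats::rnorm(m_tot * nch),
                          imaginary = stats::rnorm(m_tot * nch)),
                  m_tot, nch) * scale_rows
  spec[all_idx + 1L, ] <- coefs
  # conjugate symmetry -> real signals
  spec[n + 1L - seq_along(freq), ] <- Conj(spec[1L + seq_along(freq), ])
  signals <- Re(stats::mvfft(spec, inverse = TRUE)) / n
  colnames(signals) <- sites
  eeg_recording(signals, sampling_rate)
}

#' Default per-symptom effect specification
#'
#' Linear-Gaussian generating coefficients for each HRSD-21 item:
#' `improvement = round(beta0 + beta1 * baseline + beta2 * z(feature) + eps)`
#' with `eps ~ Normal(0, sigma)` and `z()` the within-cohort standardised EEG
#' feature.  By default one EEG effect is planted: occipital alpha power
#' (`"Oz alpha absolute"`) drives improvement in depressed mood (item 1),
#' with coefficients calibrated so that a boosted-tree model using EEG plus
#' baseline scores attains a pooled C index near 0.8 on the target item
#' while baseline scores alone attain about 0.7.
#'
#' @param planted_item HRSD item (1-21) carrying the EEG effect.
#' @param planted_feature Feature name the effect acts through (must be
#'   producible by [extract_features()]).
#' @param beta2 Planted effect size (improvement points per SD of feature).
#' @param sigma Noise SD for the planted item.
#' @return A tibble with columns `item`, `feature`, `beta0`, `beta1`,
#'   `beta2`, `sigma`.
#' @export
default_effects <- function(planted_item = 1L,
                            planted_feature = "Oz alpha absolute",
                            beta2 = -1.0, sigma = 0.97) {
  items <- hrsd_items()
  eff <- tibble::tibble(
    item = items$item,
    feature = NA_character_,
    beta0 = 0.08 * items$scale_max,
    beta1 = -0.52,
    beta2 = 0,
    sigma = 0.24 * items$scale_max
  )
  if (!is.null(planted_item)) {
    stopifnot(planted_item %in% 1:21)
    eff$feature[planted_item] <- planted_feature
    eff$beta2[planted_item] <- beta2
    eff$sigma[planted_item] <- sigma
  }
  eff
}

#' Simulation configuration for a synthetic cohort
#'
#' @param n_subjects Number of subjects (>= 2).
#' @param sampling_rate EEG sampling rate, Hz.
#' @param duration Recording length, seconds (default 120).
#' @param effects Effect specification, see [default_effects()].
#' @param baseline_mean_frac,baseline_sd_frac Mean and SD of the discretised
#'   truncated-normal baseline score distribution, as fractions of each
#'   item's scale maximum.
#' @param subject_sd Log-SD of the per-subject, per-band lognormal amplitude
#'   modifiers (between-subject band-power variability shared across sites).
#' @param site_sd Log-SD of the additional per-site, per-band lognormal
#'   jitter (regional within-subject variability).
#' @param seed Integer seed governing the whole cohort.
#' @return A `sim_config` object.
#' @export
sim_config <- function(n_subjects, sampling_rate = 250, duration = 120,
                       effects = default_effects(),
                       baseline_mean_frac = 0.6, baseline_sd_frac = 0.3,
                       subject_sd = 0.35, site_sd = 0.2, seed = 1L) {
  stopifnot(n_subjects >= 2, sampling_rate > 0, duration > 0,
            is.data.frame(effects),
            all(c("item", "feature", "beta0", "beta1", "beta2", "sigma")
                %in% names(effects)),
            all(effects$sigma >= 0), subject_sd >= 0, site_sd >= 0)
  structure(list(n_subjects = as.integer(n_subjects),
                 sampling_rate = sampling_rate, duration = duration,
                 effects = tibble::as_tibble(effects),
                 baseline_mean_frac = baseline_mean_frac,
                 baseline_sd_frac = baseline_sd_frac,
                 subject_sd = subject_sd, site_sd = site_sd,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Planted ground truth of a simulation configuration
#'
#' Pure projection of the effect specification onto the planted (nonzero)
#' EEG effects, in item order.
#'
#' @param config A [sim_config()].
#' @return A tibble with columns `item`, `feature`, `beta2`, `direction`.
#' @export
planted_truth <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  eff <- config$effects[config$effects$beta2 != 0 &
                          !is.na(config$effects$feature), ]
  eff <- eff[order(eff$item), ]
  tibble::tibble(item = eff$item, feature = eff$feature, beta2 = eff$beta2,
                 direction = ifelse(eff$beta2 < 0, "negative", "positive"))
}

# discretised truncated-normal integer scores on 0..smax
draw_baseline <- function(n, smax, mean_frac, sd_frac) {
  pmin(pmax(round(stats::rnorm(n, mean_frac * smax, sd_frac * smax)), 0L),
       smax)
}

#' Simulate a full synthetic cohort
#'
#' Generates per-subject EEG recordings (shared amplitude profile scaled by
#' per-subject, per-band lognormal modifiers), extracts their band powers,
#' then draws baseline HRSD-21 scores and generates week-8 scores through
#' the configured linear-Gaussian effect model:
#' `improvement = round(beta0 + beta1*baseline + beta2*z(feature) + eps)`,
#' clipped so the week-8 score stays on the item's scale.  The entire cohort
#' is a deterministic function of the configuration (including its seed).
#'
#' @param config A [sim_config()].
#' @param profile Site-by-band amplitude matrix; default
#'   [default_amplitude_profile()].
#' @param keep_recordings Keep the raw recordings in the result (set to
#'   `FALSE` to save memory once band powers are extracted).
#' @param window_seconds Welch window used for the internal band-power
#'   extraction.
#' @return An `eeg_cohort_sim` list with elements `scores` (wide score
#'   table), `recordings` (named list, unless dropped), `bands` (band-power
#'   table), `truth` ([planted_truth()]), `latent` (per-item pre-clipping
#'   improvements) and `clipped_fraction`.
#' @export
simulate_cohort <- function(config, profile = default_amplitude_profile(),
                            keep_recordings = TRUE, window_seconds = 2) {
  stopifnot(inherits(config, "sim_config"))
  check_profile(profile)
  eff <- config$effects
  n <- config$n_subjects
  set.seed(config$seed)
  ids <- sprintf("S%04d", seq_len(n))

  modifiers <- matrix(stats::rlnorm(n * ncol(profile), 0, config$subject_sd),
                      n, ncol(profile))
  recordings <- purrr::map(seq_len(n), function(s) {
    jitter <- matrix(stats::rlnorm(length(profile), 0, config$site_sd),
                     nrow(profile), ncol(profile))
    simulate_recording(profile * jitter *
                         rep(modifiers[s, ], each = nrow(profile)),
                       config$sampling_rate, config$duration)
  })
  names(recordings) <- ids
  bands <- band_power_table(recordings, window_seconds = window_seconds)

  planted <- unique(stats::na.omit(eff$feature))
  zfeat <- NULL
  if (length(planted) > 0) {
    combo_tbl <- purrr::map(planted, function(f) {
      feats <- feature_for_name(bands, f)
      tibble::tibble(subject_id = ids, feature = f,
                     value = feats[match(ids, feats$subject_id), ][[f]])
    })
    zfeat <- dplyr::bind_rows(combo_tbl) |>
      dplyr::group_by(.data$feature) |>
      dplyr::mutate(z = {
        s <- stats::sd(.data$value)
        if (!is.finite(s) || s == 0) {
          stop("planted feature has zero variance: ", .data$feature[1],
               call. = FALSE)
        }
        (.data$value - mean(.data$value)) / s
      }) |>
      dplyr::ungroup()
  }

  treatment <- sample(rep_len(treatment_arms(), n))
  items <- hrsd_items()
  scores <- tibble::tibble(subject_id = ids, treatment = treatment,
                           eeg_present = TRUE, features_complete = TRUE)
  latent <- list()
  n_clipped <- 0L
  for (i in items$item) {
    smax <- items$scale_max[i]
    b <- draw_baseline(n, smax, config$baseline_mean_frac,
                       config$baseline_sd_frac)
    e <- eff[eff$item == i, ]
    z <- if (!is.na(e$feature) && e$beta2 != 0) {
      zfeat$z[zfeat$feature == e$feature]
    } else 0
    raw <- round(e$beta0 + e$beta1 * b + e$beta2 * z +
                   stats::rnorm(n, 0, e$sigma))
    clipped <- pmin(pmax(raw, -b), smax - b)
    n_clipped <- n_clipped + sum(clipped != raw)
    scores[[sprintf("baseline_%02d", i)]] <- as.integer(b)
    scores[[sprintf("week8_%02d", i)]] <- as.integer(b + clipped)
    latent[[i]] <- tibble::tibble(subject_id = ids, item = i,
                                  raw_improvement = as.integer(raw),
                                  improvement = as.integer(clipped))
  }
  clipped_fraction <- n_clipped / (n * nrow(items))
  if (clipped_fraction > 0.5) {
    warning("effect specification clips ",
            sprintf("%.0f%%", 100 * clipped_fraction),
            " of improvements; configuration likely infeasible",
            call. = FALSE)
  }
  validate_scores(scores)
  structure(list(scores = scores,
                 recordings = if (keep_recordings) recordings,
                 bands = bands, truth = planted_truth(config),
                 latent = dplyr::bind_rows(latent),
                 clipped_fraction = clipped_fraction,
                 config = config),
            class = "eeg_cohort_sim")
}

#' @export
print.eeg_cohort_sim <- function(x, ...) {
  cat(sprintf(paste0("<eeg_cohort_sim> %d subjects, %d planted effect(s), ",
                     "%.1f%% clipped\n"),
              x$config$n_subjects, nrow(x$truth), 100 * x$clipped_fraction))
  invisible(x)
}

# resolve a single "<site> <band> <absolute|relative>" (or derived) feature
# name into a one-column-per-subject tibble via extract_features()
feature_for_name <- function(bands, name) {
  parts <- strsplit(name, " ", fixed = TRUE)[[1]]
  combo <- if (length(parts) == 3 && parts[2] %in% eeg_bands()$band) {
    feature_combination(parts[3], parts[2], "all")
  } else if (grepl("asymmetry$", name)) {
    feature_combination(parts[3], "alpha", "all", include_asymmetry = TRUE)
  } else if (grepl("ratio$", name)) {
    feature_combination(parts[3], c("alpha", "beta"), "all",
                        include_beta_alpha_ratio = TRUE)
  } else {
    stop("cannot parse feature name: ", name, call. = FALSE)
  }
  feats <- extract_features(bands, combo)
  if (!name %in% names(feats)) {
    stop("feature not producible: ", name, call. = FALSE)
  }
  feats[c("subject_id", name)]
}
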