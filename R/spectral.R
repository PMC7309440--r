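#' Construct a multichannel EEG recording
#'
#' @param signals Numeric matrix, samples in rows, one column per site
#'   (column names are montage labels, legacy aliases allowed), in microvolts.
#' @param sampling_rate Sampling rate in Hz.
#' @param condition Recording condition; the analysis assumes eyes-closed
#'   resting state.
#' @return An `eeg_recording` object.
#' @export
eeg_recording <- function(signals, sampling_rate,
                          condition = "eyes_closed") {
  stopifnot(is.matrix(signals), is.numeric(signals),
            length(sampling_rate) == 1, sampling_rate > 0)
  if (is.null(colnames(signals))) {
    stop("signal matrix must carry site labels as column names",
         call. = FALSE)
  }
  colnames(signals) <- resolve_site(colnames(signals))
  structure(list(signals = signals, sampling_rate = sampling_rate,
                 condition = condition),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d sites x %.1f s @ %g Hz (%s)\n",
              ncol(x$signals), nrow(x$signals) / x$sampling_rate,
              x$sampling_rate, x$condition))
  invisible(x)
}

# periodic Hanning window
hann_window <- function(n) 0.5 * (1 - cos(2 * pi * (0:(n - 1)) / n))

#' Welch power spectral density estimate
#'
#' Averaged Hanning-tapered periodogram over successive overlapping windows.
#' Each window is demeaned before tapering (so DC offsets do not leak into
#' the delta band) and the density is normalised so that its integral over
#' frequency approximates the signal variance (Parseval).  The density is
#' evaluated on a zero-padded frequency grid (`pad_factor` times finer than
#' the window's natural resolution); padding does not change the integrated
#' power but renders narrowband peaks smooth enough for stable Simpson-rule
#' band integration.
#'
#' @param x Numeric signal vector (microvolts).
#' @param sampling_rate Sampling rate in Hz.
#' @param window_seconds Welch window length in seconds (default 2 s, i.e.
#'   0.5 Hz natural resolution, the smallest window resolving the 0.5 Hz
#'   delta lower edge).
#' @param overlap_fraction Fractional overlap of successive windows
#'   (default 0.5).
#' @param pad_factor Zero-padding factor for the frequency grid (default 2).
#' @return A tibble of class `psd_tbl` with columns `frequency` (Hz, from 0
#'   to Nyquist) and `density` (microvolts squared per Hz).
#' @export
welch_psd <- function(x, sampling_rate, window_seconds = 2,
                      overlap_fraction = 0.5, pad_factor = 2) {
  m <- welch_psd_matrix(matrix(x, ncol = 1), sampling_rate, window_seconds,
                        overlap_fraction, pad_factor)
  out <- tibble::tibble(frequency = m$frequency, density = m$density[, 1])
  class(out) <- c("psd_tbl", class(out))
  out
}

# Welch PSD for all columns of a signal matrix at once; returns
# list(frequency, density matrix [freq x channel])
welch_psd_matrix <- function(signals, sampling_rate, window_seconds = 2,
                             overlap_fraction = 0.5, pad_factor = 2) {
  stopifnot(sampling_rate > 0, window_seconds > 0,
            overlap_fraction >= 0, overlap_fraction < 1, pad_factor >= 1)
  n <- nrow(signals)
  nperseg <- round(window_seconds * sampling_rate)
  if (n < nperseg) {
    stop("signal shorter than one Welch window (", nperseg, " samples)",
         call. = FALSE)
  }
  step <- max(1L, round(nperseg * (1 - overlap_fraction)))
  starts <- seq.int(1L, n - nperseg + 1L, by = step)
  w <- hann_window(nperseg)
  nfft <- as.integer(round(pad_factor * nperseg))
  half <- nfft %/% 2L
  scale <- 1 / (sampling_rate * sum(w^2))
  seg_idx <- outer(0:(nperseg - 1L), starts, `+`)  # nperseg x nseg
  nseg <- length(starts)
  nch <- ncol(signals)
  # gather every window of every channel into one matrix so the FFT work is
  # a single batched call per recording
  segs <- matrix(signals[rep(as.vector(seg_idx), nch) +
                           rep((seq_len(nch) - 1L) * n,
                               each = nperseg * nseg)],
                 nrow = nperseg)
  segs <- (segs - rep(colMeans(segs), each = nperseg)) * w
  padded <- rbind(segs, matrix(0, nfft - nperseg, ncol(segs)))
  spec <- stats::mvfft(padded)
  spec <- Mod(spec[seq_len(half + 1L), , drop = FALSE])^2
  pool <- matrix(0, nseg * nch, nch)  # window-averaging within channel
  pool[cbind(seq_len(nseg * nch), rep(seq_len(nch), each = nseg))] <- 1 / nseg
  dens <- (spec %*% pool) * scale
  # one-sided density: double everything except DC and Nyquist
  dens[2:half, ] <- 2 * dens[2:half, ]
  colnames(dens) <- colnames(signals)
  list(frequency = (0:half) * sampling_rate / nfft, density = dens)
}

# Composite Simpson quadrature weights for sampled ordinates at abscissae x
# (possibly non-uniform).  Integrating is then sum(w * y); exact for
# quadratics on each point triple, with a trapezoid closing panel when the
# number of intervals is odd.
simpson_weights <- function(x) {
  n <- length(x)
  if (n < 2) stop("need at least two points to integrate", call. = FALSE)
  w <- numeric(n)
  i <- 1L
  while (i + 2L <= n) {
    h0 <- x[i + 1L] - x[i]
    h1 <- x[i + 2L] - x[i + 1L]
    s <- (h0 + h1) / 6
    w[i] <- w[i] + s * (2 - h1 / h0)
    w[i + 1L] <- w[i + 1L] + s * (h0 + h1)^2 / (h0 * h1)
    w[i + 2L] <- w[i + 2L] + s * (2 - h0 / h1)
    i <- i + 2L
  }
  if (i + 1L == n) {  # one interval left: trapezoid
    h <- x[n] - x[n - 1L]
    w[n - 1L] <- w[n - 1L] + h / 2
    w[n] <- w[n] + h / 2
  }
  w
}

#' Absolute band power by Simpson-rule integration
#'
#' Integrates the spectral density over a frequency band using composite
#' Simpson quadrature, restricted to the available frequency bins.
#'
#' @param psd A `psd_tbl` (or any data frame with `frequency` and `density`).
#' @param band Either a canonical band name (see [eeg_bands()]) or a numeric
#'   `c(f_lo, f_hi)` pair in Hz.
#' @return Absolute power in microvolts squared.
#' @export
#' @examples
#' psd <- tibble::tibble(frequency = seq(0, 20, 0.5), density = 1)
#' band_power(psd, "theta")  # constant density 1 over 4 Hz -> 4
band_power <- function(psd, band) {
  if (is.character(band)) {
    def <- eeg_bands()[eeg_bands()$band == band, ]
    if (nrow(def) == 0) stop("unknown band: ", band, call. = FALSE)
    band <- c(def$f_lo, def$f_hi)
  }
  stopifnot(is.numeric(band), length(band) == 2, band[1] < band[2])
  idx <- which(psd$frequency >= band[1] - 1e-9 &
                 psd$frequency <= band[2] + 1e-9)
  if (length(idx) < 2) {
    stop("band [", band[1], ", ", band[2],
         "] Hz overlaps fewer than two frequency bins", call. = FALSE)
  }
  sum(simpson_weights(psd$frequency[idx]) * psd$density[idx])
}

#' Relative band powers
#'
#' Divides each of the five canonical band powers by their sum, so the five
#' fractions sum to one.
#'
#' @param powers Numeric vector of the five absolute band powers (delta,
#'   theta, alpha, beta, gamma order if unnamed).
#' @return Numeric vector of fractions summing to 1.
#' @export
relative_power <- function(powers) {
  stopifnot(is.numeric(powers), length(powers) == 5, all(powers >= 0))
  total <- sum(powers)
  if (total <= 0) stop("zero total power", call. = FALSE)
  powers / total
}

#' Per-site band-power table for a set of recordings
#'
#' Computes the Welch density once per site and the Simpson-rule absolute
#' power in each of the five canonical bands, plus the relative powers
#' (each band divided by the sum of the five).  Bands extending past the
#' Nyquist frequency are truncated to the available support.
#'
#' @param recordings A named list of [eeg_recording()] objects (names are
#'   subject ids), or a single recording.
#' @param window_seconds,overlap_fraction,pad_factor Passed to [welch_psd()].
#' @return A tibble with columns `subject_id`, `site`, `band`, `absolute`,
#'   `relative`.
#' @export
band_power_table <- function(recordings, window_seconds = 2,
                             overlap_fraction = 0.5, pad_factor = 2) {
  if (inherits(recordings, "eeg_recording")) {
    recordings <- list(subject = recordings)
  }
  stopifnot(length(recordings) > 0, !is.null(names(recordings)))
  bands <- eeg_bands()
  rows <- purrr::imap(recordings, function(rec, id) {
    stopifnot(inherits(rec, "eeg_recording"))
    psd <- welch_psd_matrix(rec$signals, rec$sampling_rate, window_seconds,
                            overlap_fraction, pad_factor)
    nyq <- rec$sampling_rate / 2
    wts <- purrr::map(seq_len(nrow(bands)), function(b) {
      hi <- min(bands$f_hi[b], nyq)
      idx <- which(psd$frequency >= bands$f_lo[b] - 1e-9 &
                     psd$frequency <= hi + 1e-9)
      if (length(idx) < 2) {
        stop("sampling rate ", rec$sampling_rate,
             " Hz leaves no support for the ", bands$band[b], " band",
             call. = FALSE)
      }
      list(idx = idx, w = simpson_weights(psd$frequency[idx]))
    })
    absolute <- vapply(wts, function(bw) {
      colSums(bw$w * psd$density[bw$idx, , drop = FALSE])
    }, numeric(ncol(psd$density)))  # site x band
    if (is.null(dim(absolute))) absolute <- matrix(absolute, nrow = 1)
    absolute <- pmax(absolute, 0)
    totals <- rowSums(absolute)
    rel <- absolute / ifelse(totals > 0, totals, NA_real_)
    rel[totals == 0, ] <- 0
    tibble::tibble(
      subject_id = id,
      site = rep(colnames(rec$signals), times = nrow(bands)),
      band = rep(bands$band, each = ncol(rec$signals)),
      absolute = as.vector(absolute),
      relative = as.vector(rel)
    )
  })
  dplyr::bind_rows(rows)
}

#' Frontal alpha asymmetry
#'
#' Alpha power at the right frontal site F4 minus the homologous left site
#' F3, per subject.
#'
#' @param bands A band-power table from [band_power_table()].
#' @param power_type `"absolute"` or `"relative"`.
#' @return A tibble with columns `subject_id` and `alpha_asymmetry`.
#' @export
alpha_asymmetry <- function(bands, power_type = c("absolute", "relative")) {
  power_type <- match.arg(power_type)
  alpha <- bands[bands$band == "alpha" & bands$site %in% c("F3", "F4"), ]
  wide <- tidyr::pivot_wider(alpha[c("subject_id", "site", power_type)],
                             names_from = "site",
                             values_from = dplyr::all_of(power_type))
  if (!all(c("F3", "F4") %in% names(wide)) || anyNA(wide[c("F3", "F4")])) {
    stop("alpha power at F3 and F4 required for the asymmetry feature",
         call. = FALSE)
  }
  tibble::tibble(subject_id = wide$subject_id,
                 alpha_asymmetry = wide$F4 - wide$F3)
}

# sentinel for beta/alpha when alpha power is numerically zero; monotone and
# finite so tree models can still split on it
.ratio_sentinel <- 1e12

#' Per-site beta-alpha power ratio
#'
#' Beta power divided by alpha power at each site, for the requested power
#' type.  Sites with alpha power below `1e-12` receive a large finite
#' sentinel value (with a warning) rather than failing the cohort.
#'
#' @inheritParams alpha_asymmetry
#' @param sites Optional character vector restricting the sites.
#' @return A tibble with columns `subject_id`, `site`, `ratio`.
#' @export
beta_alpha_ratio <- function(bands, sites = NULL,
                             power_type = c("absolute", "relative")) {
  power_type <- match.arg(power_type)
  sub <- bands[bands$band %in% c("alpha", "beta"), ]
  if (!is.null(sites)) sub <- sub[sub$site %in% resolve_site(sites), ]
  wide <- tidyr::pivot_wider(sub[c("subject_id", "site", "band", power_type)],
                             names_from = "band",
                             values_from = dplyr::all_of(power_type))
  degenerate <- wide$alpha < 1e-12
  if (any(degenerate)) {
    warning(sum(degenerate), " site(s) with near-zero alpha power; ",
            "beta-alpha ratio set to sentinel ", .ratio_sentinel,
            call. = FALSE)
  }
  tibble::tibble(subject_id = wide$subject_id, site = wide$site,
                 ratio = ifelse(degenerate, .ratio_sentinel,
                                wide$beta / wide$alpha))
}

#' Define a feature combination
#'
#' A point in the EEG feature search space: absolute or relative power, a
#' nonempty subset of the five canonical bands, a region filter (all sites,
#' frontal F7/F3/Fz/F4/F8, occipital O1/Oz/O2, or both), and flags for the
#' frontal alpha asymmetry and per-site beta-alpha ratio features.
#'
#' @param power_type `"absolute"` or `"relative"`.
#' @param bands Character vector, nonempty subset of
#'   `c("delta","theta","alpha","beta","gamma")`.
#' @param region_filter One of `"all"`, `"frontal"`, `"occipital"`,
#'   `"frontal+occipital"`.
#' @param include_asymmetry Add the F4-F3 alpha asymmetry feature.
#' @param include_beta_alpha_ratio Add per-site beta-alpha ratio features.
#' @return A `feature_combination` object.
#' @export
feature_combination <- function(power_type = c("absolute", "relative"),
                                bands = "alpha",
                                region_filter = "all",
                                include_asymmetry = FALSE,
                                include_beta_alpha_ratio = FALSE) {
  power_type <- match.arg(power_type)
  canonical <- eeg_bands()$band
  stopifnot(length(bands) > 0, all(bands %in% canonical),
            region_filter %in% region_filter_levels(),
            is.logical(include_asymmetry),
            is.logical(include_beta_alpha_ratio))
  structure(list(power_type = power_type,
                 bands = canonical[canonical %in% bands],
                 region_filter = region_filter,
                 include_asymmetry = include_asymmetry,
                 include_beta_alpha_ratio = include_beta_alpha_ratio),
            class = "feature_combination")
}

#' @export
format.feature_combination <- function(x, ...) {
  extras <- c(if (x$include_asymmetry) "asymmetry",
              if (x$include_beta_alpha_ratio) "beta-alpha ratio")
  paste0(x$power_type, " ", paste(x$bands, collapse = "+"), " @ ",
         x$region_filter,
         if (length(extras)) paste0(" +", paste(extras, collapse = "+")))
}

#' @export
print.feature_combination <- function(x, ...) {
  cat("<feature_combination> ", format(x), "\n", sep = "")
  invisible(x)
}

#' Extract the feature table implied by a feature combination
#'
#' One row per subject; columns are exactly the features implied by the
#' combination, named `"<site> <band> <absolute|relative>"` (e.g.
#' `"Fz alpha absolute"`), plus `"F4-F3 alpha <type> asymmetry"` and
#' `"<site> beta-alpha <type> ratio"` when the corresponding flags are set.
#'
#' @param x A band-power table from [band_power_table()], or a (named list
#'   of) [eeg_recording()] objects.
#' @param combination A [feature_combination()].
#' @param ... Passed to [band_power_table()] when `x` holds recordings.
#' @return A tibble with `subject_id` followed by the feature columns.
#' @export
extract_features <- function(x, combination, ...) {
  stopifnot(inherits(combination, "feature_combination"))
  bands <- if (is.data.frame(x)) tibble::as_tibble(x) else
    band_power_table(x, ...)
  sites <- region_filter_sites(combination$region_filter)
  missing_sites <- setdiff(sites, unique(bands$site))
  if (length(missing_sites) > 0) {
    stop("band-power table lacks site(s): ",
         paste(missing_sites, collapse = ", "), call. = FALSE)
  }
  ptype <- combination$power_type
  sel <- bands[bands$site %in% sites & bands$band %in% combination$bands,
               c("subject_id", "site", "band", ptype)]
  sel$feature <- paste(sel$site, sel$band, ptype)
  # deterministic column order: montage order within canonical band order
  lev <- as.vector(outer(sites, combination$bands,
                         function(s, b) paste(s, b, ptype)))
  sel$feature <- factor(sel$feature, levels = lev)
  out <- tidyr::pivot_wider(sel[c("subject_id", "feature", ptype)],
                            names_from = "feature", names_sort = FALSE,
                            names_expand = TRUE,
                            values_from = dplyr::all_of(ptype))
  if (combination$include_asymmetry) {
    asym <- alpha_asymmetry(bands, ptype)
    names(asym)[2] <- paste0("F4-F3 alpha ", ptype, " asymmetry")
    out <- dplyr::left_join(out, asym, by = "subject_id")
  }
  if (combination$include_beta_alpha_ratio) {
    rat <- beta_alpha_ratio(bands, sites, ptype)
    rat$feature <- factor(paste(rat$site, "beta-alpha", ptype, "ratio"),
                          levels = paste(sites, "beta-alpha", ptype, "ratio"))
    rat <- tidyr::pivot_wider(rat[c("subject_id", "feature", "ratio")],
                              names_from = "feature", names_sort = FALSE,
                              names_expand = TRUE, values_from = "ratio")
    out <- dplyr::left_join(out, rat, by = "subject_id")
  }
  if (anyNA(out)) stop("incomplete feature table", call. = FALSE)
  out
}

#' Read and write EEG recordings as CSV matrices
#'
#' The documented CSV dialect for a recording: a first comment line
#' `# eegboost-eeg sampling_rate_hz=<fs> condition=<condition>`, then a
#' comma-separated matrix with a header row of site labels and one row per
#' sample (microvolts).
#'
#' @param path CSV file path.
#' @return `read_eeg_csv()` returns an [eeg_recording()]; `write_eeg_csv()`
#'   returns `path` invisibly.
#' @export
read_eeg_csv <- function(path) {
  meta <- readLines(path, n = 1L)
  if (!grepl("^# eegboost-eeg ", meta)) {
    stop("not an eegboost EEG CSV: ", path, call. = FALSE)
  }
  fs <- as.numeric(sub(".*sampling_rate_hz=([0-9.eE+-]+).*", "\\1", meta))
  cond <- sub(".*condition=(\\S+).*", "\\1", meta)
  dat <- readr::read_csv(path, skip = 1, show_col_types = FALSE,
                         progress = FALSE)
  eeg_recording(as.matrix(dat), fs, cond)
}

#' @rdname read_eeg_csv
#' @param recording An [eeg_recording()].
#' @export
write_eeg_csv <- function(recording, path) {
  stopifnot(inherits(recording, "eeg_recording"))
  writeLines(sprintf("# eegboost-eeg sampling_rate_hz=%.10g condition=%s",
                     recording$sampling_rate, recording$condition), path)
  readr::write_csv(tibble::as_tibble(recording$signals), path,
                   append = TRUE, col_names = TRUE, progress = FALSE)
  invisible(path)
}
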