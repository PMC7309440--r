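#' The 26-site resting EEG montage
#'
#' Standard 10-20/10-10 labels for the 26 recording sites used throughout the
#' package, grouped into the five scalp regions (frontal, temporal, central,
#' parietal, occipital).
#'
#' @return A tibble with columns `site` and `region`.
#' @export
#' @examples
#' eeg_montage()
eeg_montage <- function() {
  tibble::tibble(
    site = c(
      "Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8",
      "FC3", "FCz", "FC4",
      "T7", "C3", "Cz", "C4", "T8",
      "CP3", "CPz", "CP4",
      "P7", "P3", "Pz", "P4", "P8",
      "O1", "Oz", "O2"
    ),
    region = c(
      rep("frontal", 7),
      rep("central", 3),
      "temporal", rep("central", 3), "temporal",
      rep("central", 3),
      rep("parietal", 5),
      rep("occipital", 3)
    )
  )
}

# legacy 10-20 aliases: T3/T4/T5/T6 are the modern T7/T8/P7/P8
site_alias_map <- c(T3 = "T7", T4 = "T8", T5 = "P7", T6 = "P8")

#' Resolve EEG site labels through the legacy alias map
#'
#' Legacy 10-20 labels T3, T4, T5 and T6 are mapped to their modern
#' equivalents T7, T8, P7 and P8; all other labels pass through unchanged.
#' Unknown labels (not in the montage after aliasing) raise an error.
#'
#' @param labels Character vector of site labels.
#' @return Character vector of canonical montage labels.
#' @export
#' @examples
#' resolve_site(c("T3", "Fz", "T6"))
resolve_site <- function(labels) {
  stopifnot(is.character(labels))
  out <- ifelse(labels %in% names(site_alias_map),
                unname(site_alias_map[labels]), labels)
  bad <- setdiff(out, eeg_montage()$site)
  if (length(bad) > 0) {
    stop("unresolvable site label(s): ", paste(unique(bad), collapse = ", "),
         call. = FALSE)
  }
  out
}

#' Canonical EEG frequency bands
#'
#' The five canonical quantitative-EEG bands: delta 0.5-4 Hz, theta 4-8 Hz,
#' alpha 8-12 Hz, beta 12-30 Hz, gamma 30-100 Hz.
#'
#' @return A tibble with columns `band`, `f_lo`, `f_hi` (Hz).
#' @export
eeg_bands <- function() {
  tibble::tibble(
    band = c("delta", "theta", "alpha", "beta", "gamma"),
    f_lo = c(0.5, 4, 8, 12, 30),
    f_hi = c(4, 8, 12, 30, 100)
  )
}

# site sets used by the region filter of a feature combination
region_filter_sites <- function(region_filter) {
  montage <- eeg_montage()$site
  frontal <- c("F7", "F3", "Fz", "F4", "F8")
  occipital <- c("O1", "Oz", "O2")
  switch(region_filter,
    all = montage,
    frontal = frontal,
    occipital = occipital,
    `frontal+occipital` = c(frontal, occipital),
    stop("unknown region filter: ", region_filter, call. = FALSE)
  )
}

region_filter_levels <- function() {
  c("all", "frontal", "occipital", "frontal+occipital")
}
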