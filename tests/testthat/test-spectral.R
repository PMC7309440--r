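fs <- 250

test_that("Welch density integrates to the signal variance (Parseval)", {
  set.seed(1)
  ratios <- replicate(3, {
    x <- rnorm(120 * fs)
    psd <- welch_psd(x, fs)
    band_power(psd, c(0, fs / 2)) / stats::var(x)
  })
  expect_true(all(abs(ratios - 1) < 0.05))
})

test_that("Welch handles degenerate signals", {
  expect_equal(max(welch_psd(rep(0, 1000), fs)$density), 0)
  expect_error(welch_psd(rnorm(100), fs, window_seconds = 2), "shorter")
})

test_that("a pure sinusoid concentrates its analytic power in its band", {
  t <- seq(0, 60 - 1 / fs, by = 1 / fs)
  a <- 3
  psd <- welch_psd(a * sin(2 * pi * 10 * t), fs)
  pows <- vapply(eeg_bands()$band, function(b) band_power(psd, b),
                 numeric(1))
  expect_lt(abs(pows[["alpha"]] - a^2 / 2) / (a^2 / 2), 0.02)
  expect_true(all(pows[c("delta", "theta", "beta", "gamma")] <
                    0.05 * pows[["alpha"]]))
  expect_gt(relative_power(pows)[["alpha"]], 0.9)
})

test_that("Simpson band power: exact for constants, near a fine trapezoid", {
  flat <- tibble::tibble(frequency = seq(0, 20, 0.5), density = 2.5)
  expect_equal(band_power(flat, "theta"), 4 * 2.5)
  # smooth density on an odd-sized grid vs refined trapezoid
  f <- seq(8, 12, length.out = 21)
  dens <- exp(-f / 10) * (1 + 0.3 * sin(f))
  coarse <- band_power(tibble::tibble(frequency = f, density = dens),
                       c(8, 12))
  ff <- seq(8, 12, length.out = 4001)
  densf <- exp(-ff / 10) * (1 + 0.3 * sin(ff))
  fine <- sum(diff(ff) * (densf[-1] + densf[-length(densf)]) / 2)
  expect_lt(abs(coarse - fine) / fine, 0.001)
  expect_error(band_power(flat, c(30, 40)), "fewer than two")
})

test_that("relative powers are fractions of the five-band total", {
  expect_equal(relative_power(rep(1, 5)), rep(0.2, 5))
  expect_equal(relative_power(c(0, 0, 4, 0, 0)), c(0, 0, 1, 0, 0))
  set.seed(2)
  for (i in 1:20) {
    p <- stats::rlnorm(5)
    expect_lt(abs(sum(relative_power(p)) - 1), 1e-9)
  }
  expect_error(relative_power(rep(0, 5)), "zero total")
})

test_that("alpha asymmetry is F4 minus F3 and antisymmetric", {
  bands <- fake_band_table(4, seed = 3)
  asym <- alpha_asymmetry(bands)
  manual <- tidyr::pivot_wider(
    bands[bands$band == "alpha" & bands$site %in% c("F3", "F4"),
          c("subject_id", "site", "absolute")],
    names_from = "site", values_from = "absolute")
  expect_equal(asym$alpha_asymmetry, manual$F4 - manual$F3)
  # identical channels -> zero; swapping channels negates
  bands2 <- bands
  f3 <- bands2$site == "F3" & bands2$band == "alpha"
  f4 <- bands2$site == "F4" & bands2$band == "alpha"
  tmp <- bands2$absolute[f3]
  bands2$absolute[f3] <- bands2$absolute[f4]
  bands2$absolute[f4] <- tmp
  expect_equal(alpha_asymmetry(bands2)$alpha_asymmetry,
               -asym$alpha_asymmetry)
  same <- bands
  same$absolute[f4] <- same$absolute[f3]
  expect_true(all(alpha_asymmetry(same)$alpha_asymmetry == 0))
})

test_that("beta-alpha ratio divides beta by alpha with a sentinel policy", {
  bands <- fake_band_table(2, seed = 4)
  bands$absolute[bands$site == "Fz" & bands$band == "beta"] <- 3
  bands$absolute[bands$site == "Fz" & bands$band == "alpha"] <- 1.5
  rat <- beta_alpha_ratio(bands, sites = "Fz")
  expect_equal(rat$ratio, c(2, 2))
  bands$absolute[bands$site == "Cz" & bands$band == "alpha"] <- 0
  expect_warning(rz <- beta_alpha_ratio(bands, sites = "Cz"),
                 "near-zero alpha")
  expect_true(all(rz$ratio == 1e12))
})

test_that("extract_features yields exactly the implied columns", {
  bands <- fake_band_table(5, seed = 5)
  occ <- extract_features(bands,
                          feature_combination("absolute", "alpha",
                                              "occipital"))
  expect_equal(names(occ),
               c("subject_id", "O1 alpha absolute", "Oz alpha absolute",
                 "O2 alpha absolute"))
  all_rel <- extract_features(bands,
                              feature_combination("relative",
                                                  eeg_bands()$band, "all"))
  expect_equal(ncol(all_rel), 1 + 26 * 5)
  with_asym <- extract_features(bands,
    feature_combination("absolute", "alpha", "occipital",
                        include_asymmetry = TRUE))
  expect_equal(ncol(with_asym), ncol(occ) + 1)
  expect_true("F4-F3 alpha absolute asymmetry" %in% names(with_asym))
  with_ratio <- extract_features(bands,
    feature_combination("relative", c("alpha", "beta"), "frontal",
                        include_beta_alpha_ratio = TRUE))
  expect_equal(ncol(with_ratio), 1 + 5 * 2 + 5)
  expect_error(
    extract_features(bands[bands$site != "Oz", ],
                     feature_combination("absolute", "alpha", "occipital")),
    "lacks site")
})

test_that("absolute powers scale as amplitude^2; relative are scale-free", {
  prof <- pure_profile("alpha", 5, sites = c("F3", "F4", "O1"))
  prof[, "beta"] <- 2
  rec <- simulate_recording(prof, fs, 10, seed = 9)
  c_scale <- 3
  rec2 <- eeg_recording(rec$signals * c_scale, fs)
  b1 <- band_power_table(rec)
  b2 <- band_power_table(rec2)
  expect_equal(b2$absolute, b1$absolute * c_scale^2, tolerance = 1e-10)
  expect_equal(b2$relative, b1$relative, tolerance = 1e-6)
  r1 <- beta_alpha_ratio(b1, "O1")
  r2 <- beta_alpha_ratio(b2, "O1")
  expect_equal(r1$ratio, r2$ratio, tolerance = 1e-6)
})

test_that("legacy site aliases resolve and unknown labels fail", {
  expect_equal(resolve_site(c("T3", "T4", "T5", "T6")),
               c("T7", "T8", "P7", "P8"))
  expect_error(resolve_site("XX"), "unresolvable")
  sig <- matrix(rnorm(500 * 2), 500, 2,
                dimnames = list(NULL, c("T3", "Oz")))
  rec <- eeg_recording(sig, fs)
  expect_equal(colnames(rec$signals), c("T7", "Oz"))
})

test_that("EEG recordings round-trip through the CSV matrix dialect", {
  rec <- simulate_recording(pure_profile("alpha", 2, c("O1", "Oz")),
                            128, 4, seed = 1)
  path <- withr::local_tempfile(fileext = ".csv")
  write_eeg_csv(rec, path)
  back <- read_eeg_csv(path)
  expect_equal(back$sampling_rate, 128)
  expect_equal(colnames(back$signals), colnames(rec$signals))
  expect_equal(back$signals, rec$signals, tolerance = 1e-12)
})
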