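fx <- default_ubiquitin_fixture()

test_that("ratio, delta and their errors follow the propagation formulas", {
  expect_equal(ratio_r(1, 1), 1)
  expect_equal(ratio_r(0.8, 1.0), 0.8)
  expect_error(ratio_r(1, 0), "positive")

  expect_equal(error_r(1, 33.3, 33.3), sqrt(2) / 33.3)
  expect_equal(error_r(0.8, 50, 40), 0.8 * sqrt(0.0004 + 0.000625))
  expect_equal(error_r(1, Inf, Inf), 0)
  expect_error(error_r(1, -5, 10), "positive")

  expect_equal(delta_r(1, 1), 0)
  expect_equal(delta_r(0.9, 1.0), -0.1)
  expect_equal(delta_r(0.93, 1.07), -delta_r(1.07, 0.93)) # antisymmetry

  expect_equal(error_delta_r(0, 0, "quadrature"), 0)
  expect_equal(error_delta_r(0, 0, "sum"), 0)
  expect_equal(error_delta_r(0.03, 0.04), 0.05)
  expect_equal(error_delta_r(0.03, 0.04, "sum"), 0.07)
  expect_equal(error_delta_r(0.03, 0.04, "half_sum"), 0.035)
  expect_error(error_delta_r(0.1, 0.1, "geometric"), "arg")
})

test_that("ratio error matches the Monte-Carlo noisy-signal oracle", {
  set.seed(99)
  grid <- expand.grid(r = c(0.8, 1, 1.2), snr = c(20, 33.3, 100))
  for (i in seq_len(nrow(grid))) {
    r <- grid$r[i]; snr <- grid$snr[i]
    mc <- oracle_ratio_error_mc(r, snr, snr, n = 1e5)
    expect_equal(error_r(r, snr, snr), mc, tolerance = 0.05)
  }
})

test_that("the one-sigma rule is strict, exhaustive and monotone", {
  expect_equal(classify_delta(-0.10, 0.05), "accelerated")
  expect_equal(classify_delta(0.10, 0.05), "decelerated")
  expect_equal(classify_delta(-0.05, 0.05), "unchanged") # boundary is strict
  expect_equal(classify_delta(0.05, 0.05), "unchanged")
  expect_equal(classify_delta(0, 0), "unchanged")

  # monotone in delta at fixed error; unchanged iff |delta| <= error
  deltas <- seq(-0.2, 0.2, by = 0.001)
  lab <- classify_delta(deltas, 0.05)
  expect_true(all(lab == "unchanged") == FALSE)
  ord <- match(lab, c("accelerated", "unchanged", "decelerated"))
  expect_true(all(diff(ord) >= 0))
  expect_equal(lab == "unchanged", abs(deltas) <= 0.05)
})

test_that("6/12-min calls merge into the dark/light onset tiers", {
  both <- combine_timepoints("accelerated", "accelerated")
  expect_equal(both$label, "accelerated")
  expect_equal(both$onset, "at_6_and_12")

  late <- combine_timepoints("unchanged", "decelerated")
  expect_equal(late$label, "decelerated")
  expect_equal(late$onset, "only_12")

  gone <- combine_timepoints("accelerated", "unchanged")
  expect_equal(gone$label, "unchanged")
  expect_equal(gone$onset, "none")

  expect_warning(
    conf <- combine_timepoints("accelerated", "decelerated"),
    "conflict"
  )
  expect_equal(conf$label, "unchanged")
  expect_equal(conf$onset, "none")
})

test_that("methyl normalisation cancels concentration jitter exactly", {
  # scale invariance of a whole sample
  tab <- simulate_experiment(
    fx, experiment_design("GC", 3, nominal_snr = Inf, seed = 2),
    gc_scenario(), conc_jitter_sd = 0
  )
  scaled <- dplyr::mutate(tab, intensity = intensity * 3.7)
  n1 <- normalize_intensities(tab)
  n2 <- normalize_intensities(scaled)
  expect_equal(n1$intensity_norm, n2$intensity_norm)

  # with 2% jitter and noise off, normalised amides recover the fraction
  des <- experiment_design("GC", 12, nominal_snr = Inf, seed = 4)
  jit <- simulate_experiment(fx, des, gc_scenario(), conc_jitter_sd = 0.02)
  frac <- protonated_fraction(build_schedule(des, gc_scenario()), fx)
  nj <- normalize_intensities(jit)
  expect_equal(nj$intensity_norm, frac$fraction, tolerance = 1e-9)

  expect_equal(normalize_intensities(tibble::tibble(
    signal_id = c(1L, 1L), kind = c("amide", "methyl"),
    intensity = c(1, 2), snr = c(50, 50),
    condition = "GC", timepoint_min = 3
  ))$intensity_norm, 0.5)
  expect_error(
    normalize_intensities(tibble::tibble(
      signal_id = 1L, kind = "amide", intensity = 1, snr = 50,
      condition = "GC", timepoint_min = 3
    )),
    "methyl"
  )
})

test_that("noise-free control-vs-control ratios are exactly 1", {
  tabs <- purrr::map(c(3, 6, 12), function(tp) {
    purrr::map(c("TC", "GC"), function(cond) {
      simulate_experiment(
        fx, experiment_design(cond, tp, nominal_snr = Inf,
                              seed = 100 + tp),
        gc_scenario()
      )
    })
  })
  peaks <- dplyr::bind_rows(purrr::flatten(tabs))
  ratios <- compute_ratios(peaks)
  expect_equal(ratios$r, rep(1, nrow(ratios)), tolerance = 1e-12)
  cls <- classify_residues(ratios)
  expect_true(all(cls$label == "unchanged"))
})

test_that("residue selection excludes fast exchangers, low SNR and overlap", {
  res <- dplyr::bind_rows(
    fx,
    tibble::tibble(residue_number = 8L, amino_acid = "L",
                   hydropathy_class = "hydrophilic_surface",
                   K_op = 1e-3, k_ch_ref = 2e4, # k_ex = 20 h^-1: storage wipes it
                   overlap_flag = FALSE, fast_exchanger = TRUE),
    tibble::tibble(residue_number = 23L, amino_acid = "I",
                   hydropathy_class = "hydrophobic_surface",
                   K_op = 1e-6, k_ch_ref = 3e4,
                   overlap_flag = TRUE, fast_exchanger = FALSE)
  )
  peaks <- simulate_run(res, thz_scenario(), "THz_low", nominal_snr = 100,
                        seed = 17)
  sel <- select_residues(peaks)
  expect_equal(sel$reason[sel$residue_number == 8], "fast_exchanger")
  expect_equal(sel$reason[sel$residue_number == 23], "overlap")
  expect_true(all(sel$included[!sel$residue_number %in% c(8, 23)]))

  # a residue dropping under the SNR threshold anywhere is excluded
  # (per-spectrum SNR 15 gives summed SNR ~ sqrt(3)*15 ~ 26 < 33.3)
  low <- simulate_run(res, thz_scenario(), "THz_low", nominal_snr = 15,
                      seed = 17)
  sel_low <- select_residues(low)
  expect_true(any(sel_low$reason[sel_low$included == FALSE] == "low_snr"))
  ok <- select_residues(peaks, snr_min = 33.3)
  expect_true(all(c("included", "reason") %in% names(ok)))
})

test_that("exponential rate fitting recovers known decays", {
  t <- c(0, 2, 4, 6, 8, 10)
  d <- tibble::tibble(time_h = t, intensity = 2 * exp(-0.05 * t))
  fit <- fit_hdx_rate(d, time_h, intensity)
  expect_equal(unname(coef(fit)["k"]), 0.05, tolerance = 1e-6)
  expect_equal(unname(coef(fit)["A"]), 2, tolerance = 1e-6)

  td <- tidy(fit)
  expect_setequal(td$term, c("A", "k"))
  expect_true(all(td$std.error < 1e-6))
  expect_equal(glance(fit)$nobs, 6L)

  # constant series -> k ~ 0 (bounded below at zero)
  dc <- tibble::tibble(time_h = t, intensity = rep(1.3, 6))
  expect_lt(unname(coef(fit_hdx_rate(dc, time_h, intensity))["k"]), 1e-8)

  expect_error(fit_hdx_rate(d[1:2, ], time_h, intensity), "3 points")
  expect_error(
    fit_hdx_rate(tibble::tibble(time_h = c(1, 1, 1), intensity = c(1, 2, 3)),
                 time_h, intensity),
    "degenerate"
  )
})

test_that("rate fitting is calibrated against its reported standard error", {
  # 6 points over 10 h at SNR 100. With only 4 residual degrees of freedom
  # the correct 95% interval uses the t quantile (qt(0.975, 4) ~ 2.78); the
  # plain 2-sigma interval covers ~ pt-based 88%. Both are checked.
  k_true <- 0.08
  t <- seq(0, 10, length.out = 6)
  z <- purrr::map_dbl(1:500, function(s) {
    set.seed(s)
    i <- exp(-k_true * t) + stats::rnorm(6, 0, 0.01) # SNR 100
    if (any(i <= 0)) return(NA)
    td <- tidy(fit_hdx_rate(tibble::tibble(t = t, i = i), t, i))
    abs(td$estimate[td$term == "k"] - k_true) / td$std.error[td$term == "k"]
  })
  cover_t <- mean(z <= stats::qt(0.975, df = 4), na.rm = TRUE)
  cover_2 <- mean(z <= 2, na.rm = TRUE)
  expect_gte(cover_t, 0.92)
  expect_gte(cover_2, 0.82)
  expect_lte(cover_2, 0.95)
})
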