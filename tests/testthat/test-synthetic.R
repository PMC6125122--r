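p_gerbil <- cochlea_params("gerbil")

test_that("noise-free model hits its configured ratio and compression marks", {
  s30 <- make_spectra(p_gerbil, "g1", 30, noise = FALSE)
  s80 <- make_spectra(p_gerbil, "g1", 80, noise = FALSE)
  tr30 <- transfer_ratio(s30, "RL", "BM")
  tr80 <- transfer_ratio(s80, "RL", "BM")
  expect_equal(tr30$ratio[tr30$frequency_hz == 26000], 10, tolerance = 0.01)
  expect_equal(tr80$ratio[tr80$frequency_hz == 26000], 1.5, tolerance = 0.01)
  at_bf <- function(s, st) {
    d <- dplyr::filter(s, structure == st, frequency_hz == 26000)
    d$magnitude_nm
  }
  bm_comp <- compression_db(30, 80, at_bf(s80, "BM") / at_bf(s30, "BM"))
  expect_equal(bm_comp, 23, tolerance = 0.5)
  # emergent RL compression: 23 + 20*log10(10/1.5) = 39.5 dB
  rl_comp <- compression_db(30, 80, at_bf(s80, "RL") / at_bf(s30, "RL"))
  expect_equal(rl_comp, 23 + 20 * log10(10 / 1.5), tolerance = 1)
})

test_that("phase-difference law is half a cycle at DC and linear in f", {
  expect_equal(delta_phi_law(p_gerbil, 0), 0.5, tolerance = 1e-12)
  f <- c(10, 5000, 26000)
  expect_equal(delta_phi_law(p_gerbil, f), 0.5 - f * 17.9e-6, tolerance = 1e-12)
  expect_equal(delta_phi_law(p_gerbil, f, "click"), 0.5 - f * 32.6e-6,
               tolerance = 1e-12)
  # the generated spectra carry exactly this law when noise-free
  s <- make_spectra(p_gerbil, "g1", 60, noise = FALSE)
  pd <- phase_difference_curve(s)
  expect_equal(pd$phase_diff_cycles,
               delta_phi_law(p_gerbil, pd$frequency_hz), tolerance = 1e-9)
})

test_that("postmortem mode removes the active signature", {
  spm <- make_spectra(p_gerbil, "g1", 70, state = "postmortem", noise = FALSE)
  pd <- phase_difference_curve(spm)
  # passive drag only: -f * delta_pm, no half-cycle offset
  expect_equal(pd$phase_diff_cycles, -pd$frequency_hz * p_gerbil$delta_pm_s,
               tolerance = 1e-9)
  rl <- dplyr::filter(spm, structure == "RL")
  bm <- dplyr::filter(spm, structure == "BM")
  expect_true(all(rl$magnitude_nm < bm$magnitude_nm))
  # linear growth: equal dB spacing of the postmortem level series
  m60 <- dplyr::filter(make_spectra(p_gerbil, "g1", 60, state = "postmortem",
                                    noise = FALSE), structure == "BM")
  m70 <- dplyr::filter(make_spectra(p_gerbil, "g1", 70, state = "postmortem",
                                    noise = FALSE), structure == "BM")
  expect_equal(20 * log10(m70$magnitude_nm / m60$magnitude_nm),
               rep(10, nrow(m60)), tolerance = 1e-9)
})

test_that("cohorts are reproducible and sized as designed", {
  coh1 <- make_cohort(p_gerbil, 7, c(50, 60, 70, 80), seed = 1)
  coh2 <- make_cohort(p_gerbil, 7, c(50, 60, 70, 80), seed = 1)
  expect_identical(coh1$spectra, coh2$spectra)
  n_records <- coh1$spectra |>
    dplyr::filter(structure == "RL") |>
    dplyr::distinct(animal_id, level_db_spl) |>
    nrow()
  expect_equal(n_records, 28)
  coh3 <- make_cohort(p_gerbil, 2, c(50, 60), seed = 2)
  expect_false(identical(coh1$spectra$magnitude_nm[1:10],
                         coh3$spectra$magnitude_nm[1:10]))
})

test_that("tone pipeline recovers injected latency differences", {
  for (inj in c(10e-6, 17.9e-6, 25e-6)) {
    p <- cochlea_params("gerbil", delta_tau_tone_s = inj)
    means <- vapply(1:20, function(i) {
      coh <- make_cohort(p, 3, c(50, 70), seed = 1000 + i)
      group_latency(latency_by_record(coh$spectra))$mean
    }, numeric(1))
    se <- sd(means) / sqrt(length(means))
    expect_lt(abs(mean(means) - inj * 1e6), 2 * se + 0.2)
  }
})

test_that("click pipeline recovers the injected click delay", {
  coh <- make_cohort(p_gerbil, 10, levels_db_spl = numeric(0),
                     click_levels_db_p = 90, seed = 7)
  lat <- click_latency_difference(click_features(coh$clicks))
  expect_equal(nrow(lat), 10)
  expect_lt(abs(mean(lat$delta_tau_us) - 32.6), 2)
  # degenerate pure-delay parameters: unit ratio, no slow admixture
  pd <- cochlea_params("gerbil", click_ratio = 1, click_lf_frac = 0)
  cp <- make_click_pair(pd, "g1", 90, noise = FALSE)
  lat1 <- click_latency_difference(click_features(cp))
  expect_lt(abs(lat1$delta_tau_s - 32.6e-6), 1e-6)
})

test_that("sensitive clicks oppose in polarity with an ~8-fold peak ratio", {
  cp <- make_click_pair(p_gerbil, "g1", 90, noise = FALSE)
  lat <- click_latency_difference(click_features(cp))
  expect_equal(lat$sign_bm, 1)
  expect_equal(lat$sign_rl, -1)
  expect_lt(abs(lat$peak_ratio - 8) / 8, 0.1)
  pm <- click_features(make_click_pair(p_gerbil, "g1", 90, state = "postmortem",
                                       noise = FALSE))
  mags <- pm$first_peak_magnitude_nm
  expect_lt(max(mags) / min(mags), 2)  # comparable postmortem magnitudes
})

test_that("parameter validation rejects nonsense", {
  expect_error(cochlea_params("gerbil", bf_hz = -1), "positive")
  expect_error(cochlea_params("gerbil", nonsense = 1), "unknown parameter")
  expect_error(cochlea_params("gerbil", f_max_hz = 1000), "exceed|within")
  expect_error(make_cohort(p_gerbil, 0, seed = 1), "at least 1")
  expect_error(make_cohort(p_gerbil, 2), "seed")
})
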