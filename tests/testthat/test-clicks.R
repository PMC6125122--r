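test_that("first peak of a triangle pulse is found at its apex", {
  t <- seq(0, 5e-3 - 5e-6, by = 5e-6)
  y <- pmax(0, 1 - abs(t - 400e-6) / 50e-6)  # apex exactly at 400 us
  click <- tibble::tibble(
    animal_id = "a1", species = "gerbil", state = "sensitive",
    structure = "BM", level_db_p = 90, time_s = t, displacement_nm = y
  )
  pk <- detect_first_peak(click)
  expect_equal(pk$first_peak_time_s, 400e-6, tolerance = 1e-9)
  expect_equal(pk$first_peak_sign, 1)
  neg <- dplyr::mutate(click, displacement_nm = -displacement_nm)
  pk2 <- detect_first_peak(neg)
  expect_equal(pk2$first_peak_time_s, 400e-6, tolerance = 1e-9)
  expect_equal(pk2$first_peak_sign, -1)
})

test_that("first-peak time is equivariant under integer sample shifts", {
  base <- toy_click(26000, t0 = 1e-3)
  pk0 <- detect_first_peak(base)
  for (k in c(3L, 17L)) {
    shifted <- base
    shifted$displacement_nm <- c(rep(0, k), base$displacement_nm[1:(nrow(base) - k)])
    pk <- detect_first_peak(shifted)
    expect_equal(pk$first_peak_time_s - pk0$first_peak_time_s, k * 5e-6,
                 tolerance = 1e-9)
  }
})

test_that("click features are invariant under positive rescaling", {
  base <- toy_click(26000, t0 = 1e-3)
  big <- dplyr::mutate(base, displacement_nm = 42 * displacement_nm)
  pk1 <- detect_first_peak(base); pk2 <- detect_first_peak(big)
  expect_equal(pk1$first_peak_time_s, pk2$first_peak_time_s, tolerance = 1e-12)
  expect_equal(pk1$first_peak_sign, pk2$first_peak_sign)
  expect_equal(first_period(base)$first_period_s,
               first_period(big)$first_period_s, tolerance = 1e-12)
})

test_that("undetectable records raise an informative error", {
  t <- seq(0, 5e-3 - 5e-6, by = 5e-6)
  set.seed(5)
  flat <- tibble::tibble(
    animal_id = "a1", species = "gerbil", state = "sensitive",
    structure = "BM", level_db_p = 50, time_s = t,
    displacement_nm = rnorm(length(t), 0, 1)
  )
  # pure noise: no extremum clears threshold_mult x RMS with the floor
  expect_error(detect_first_peak(flat, threshold_mult = 5), "undetectable")
})

test_that("pure-delay inverted pairs recover the delay to sub-sample precision", {
  fs <- 2e5
  t <- seq(0, 5e-3 - 1 / fs, by = 1 / fs)
  wave <- function(tt, t0) {
    ifelse(tt < t0, 0,
           exp(-(tt - t0) / 3e-4) * sin(2 * pi * 26000 * (tt - t0)))
  }
  for (tau in c(10e-6, 20e-6, 32.6e-6, 50e-6)) {
    bm <- tibble::tibble(
      animal_id = "a1", species = "gerbil", state = "sensitive",
      structure = "BM", level_db_p = 90, time_s = t,
      displacement_nm = wave(t, 1e-3)
    )
    rl <- dplyr::mutate(bm, structure = "RL",
                        displacement_nm = -wave(t, 1e-3 + tau))
    lat <- click_latency_difference(click_features(dplyr::bind_rows(rl, bm)))
    expect_lt(abs(lat$delta_tau_s - tau), 1e-6)
    expect_equal(lat$sign_rl, -lat$sign_bm)
  }
})

test_that("first period matches the generator period of decaying sinusoids", {
  p26 <- first_period(toy_click(26000, t0 = 1e-3))
  expect_lt(abs(p26$first_period_s - 1 / 26000), 0.5e-6)
  p10 <- first_period(toy_click(10000, t0 = 1e-3, tau_env = 2e-3))
  expect_lt(abs(p10$first_period_s - 100e-6), 0.5e-6)
})

test_that("in-phase time of identical records is the first post-peak sample", {
  bm <- toy_click(20000, t0 = 1e-3)
  rl <- dplyr::mutate(bm, structure = "RL")
  res <- in_phase_time(rl, bm)
  expect_true(res$defined)
  pk <- detect_first_peak(bm)
  expect_lt(abs(res$t_c_s - pk$first_peak_time_s), 5e-6)
})

test_that("a constructed antiphase drift reaches alignment at the designed time", {
  fs <- 2e5
  t <- seq(0, 5e-3 - 1 / fs, by = 1 / fs)
  t0 <- 2e-4
  env <- ifelse(t < t0, 0, exp(-(t - t0) / 2e-3))
  bm_y <- env * cos(2 * pi * 20000 * (t - t0))
  # phase difference 0.5 - 0.5 * (t - t0) / 3e-4 cycles: zero at t = 0.5 ms
  drift <- 0.5 - 0.5 * (t - t0) / 3e-4
  rl_y <- env * cos(2 * pi * 20000 * (t - t0) + 2 * pi * drift)
  bm <- tibble::tibble(
    animal_id = "a1", species = "gerbil", state = "sensitive",
    structure = "BM", level_db_p = 90, time_s = t, displacement_nm = bm_y
  )
  rl <- dplyr::mutate(bm, structure = "RL", displacement_nm = rl_y)
  res <- in_phase_time(rl, bm)
  expect_true(res$defined)
  expect_lt(abs(res$t_c_s - 5e-4), 5e-6)
})

test_that("polarity flip is detected between sensitive and postmortem presets", {
  expect_true(polarity_flip_check(-1, 1))
  expect_false(polarity_flip_check(1, 1))
  p <- cochlea_params("gerbil")
  sen <- click_features(make_click_pair(p, "g1", 90, noise = FALSE))
  pm <- click_features(make_click_pair(p, "g1", 90, state = "postmortem",
                                       noise = FALSE))
  rl_sen <- dplyr::filter(sen, structure == "RL")
  rl_pm <- dplyr::filter(pm, structure == "RL")
  expect_true(polarity_flip_check(rl_sen, rl_pm))
  bm_sen <- dplyr::filter(sen, structure == "BM")
  bm_pm <- dplyr::filter(pm, structure == "BM")
  expect_false(polarity_flip_check(bm_sen, bm_pm))
})

test_that("gerbil preset clicks show the reported first-peak geometry", {
  p <- cochlea_params("gerbil")
  fx <- click_features(make_click_pair(p, "g1", 90, noise = FALSE))
  rl <- dplyr::filter(fx, structure == "RL")
  bm <- dplyr::filter(fx, structure == "BM")
  expect_equal(rl$first_peak_sign, -1)  # toward scala tympani
  expect_equal(bm$first_peak_sign, 1)   # toward scala vestibuli
  expect_lt(abs(rl$first_peak_time_s - 0.40e-3), 0.05e-3)
  expect_gt(rl$first_period_s, bm$first_period_s)
})

test_that("validate_timeseries rejects a missing sample", {
  d <- toy_click(26000)
  broken <- d[-100, ]
  expect_error(validate_timeseries(broken), "non-uniform")
  expect_silent(validate_timeseries(d))
})
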