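test_that("phase-slope fit recovers an analytically forced latency", {
  f <- seq(2000, 26000, by = 2000)
  curve <- tibble::tibble(frequency_hz = f, phase_diff_cycles = 0.5 - 1.79e-5 * f)
  fit <- latency_from_phase_slope(curve, 2000, 26000)
  expect_equal(fit$delta_tau_s, 1.79e-5, tolerance = 1e-12)
  expect_equal(fit$n_points, 13)
  flat <- tibble::tibble(frequency_hz = f, phase_diff_cycles = rep(0.25, 13))
  expect_equal(latency_from_phase_slope(flat, 2000, 26000)$delta_tau_s, 0,
               tolerance = 1e-15)
})

test_that("fit errors on short or degenerate input", {
  curve <- tibble::tibble(frequency_hz = c(1000, 2000), phase_diff_cycles = c(0, 1))
  expect_error(latency_from_phase_slope(curve, 0, 5000), "3 usable")
  same_f <- tibble::tibble(frequency_hz = rep(1000, 4), phase_diff_cycles = 1:4)
  expect_error(latency_from_phase_slope(same_f, 0, 5000), "spread")
})

test_that("OLS slope equals the closed-form oracle; noisy mean is unbiased", {
  set.seed(1)
  f <- seq(2000, 26000, by = 2000)
  taus <- replicate(200, {
    y <- 0.5 - 1.79e-5 * f + rnorm(length(f), 0, 0.02)
    fit <- latency_from_phase_slope(
      tibble::tibble(frequency_hz = f, phase_diff_cycles = y), 2000, 26000
    )
    oracle <- ols_oracle(f, y)
    expect_equal(fit$slope_cycles_per_hz, unname(oracle["slope"]),
                 tolerance = 1e-12)
    expect_equal(fit$intercept_cycles, unname(oracle["intercept"]),
                 tolerance = 1e-12)
    fit$delta_tau_s
  })
  se <- sd(taus) / sqrt(length(taus))
  expect_lt(abs(mean(taus) - 1.79e-5), 3 * se)
})

test_that("pure delay is recovered exactly for any spectrum and fit range", {
  set.seed(7)
  for (tau in c(5e-6, 17.9e-6, 40e-6)) {
    f <- sort(runif(40, 1000, 30000))
    base_phase <- cumsum(runif(40, -0.3, 0.3))  # arbitrary smooth-ish phase
    rl <- toy_spectrum("RL", runif(40, 1, 10), base_phase - f * tau, f = f)
    bm <- toy_spectrum("BM", runif(40, 1, 10), base_phase, f = f)
    curve <- phase_difference_curve(dplyr::bind_rows(rl, bm))
    for (rng in list(c(1000, 30000), c(5000, 20000))) {
      fit <- latency_from_phase_slope(curve, rng[1], rng[2])
      expect_equal(fit$delta_tau_s, tau, tolerance = 1e-12)
    }
  }
})

test_that("latency estimate is invariant to a constant phase offset", {
  f <- seq(2000, 26000, by = 2000)
  y <- 0.2 - 2e-5 * f
  fit1 <- latency_from_phase_slope(
    tibble::tibble(frequency_hz = f, phase_diff_cycles = y), 2000, 26000)
  fit2 <- latency_from_phase_slope(
    tibble::tibble(frequency_hz = f, phase_diff_cycles = y + 0.37), 2000, 26000)
  expect_equal(fit1$delta_tau_s, fit2$delta_tau_s, tolerance = 1e-12)
})

test_that("tidy and glance expose the fit as tibbles", {
  f <- seq(2000, 26000, by = 2000)
  fit <- latency_from_phase_slope(
    tibble::tibble(frequency_hz = f, phase_diff_cycles = 0.5 - 1.79e-5 * f),
    2000, 26000
  )
  td <- tidy(fit)
  expect_equal(td$term, c("intercept_cycles", "slope_cycles_per_hz"))
  expect_equal(td$estimate[2], -1.79e-5, tolerance = 1e-12)
  gl <- glance(fit)
  expect_equal(gl$delta_tau_us, 17.9, tolerance = 1e-9)
  expect_equal(gl$r_squared, 1, tolerance = 1e-9)
})

test_that("group_latency computes mean, SEM and n", {
  g <- group_latency(c(10, 20, 30))
  expect_equal(g$mean, 20)
  expect_equal(g$sem, 10 / sqrt(3), tolerance = 1e-12)
  expect_equal(g$n, 3)
  g1 <- group_latency(42)
  expect_equal(g1$sem, 0)
  expect_equal(g1$n, 1)
  expect_error(group_latency(numeric(0)), "no estimates")
})

test_that("one-way ANOVA matches hand-computed sums of squares", {
  d0 <- tibble::tibble(delta_tau_us = c(1, 2, 3, 1, 2, 3),
                       level_db_spl = rep(c(50, 60), each = 3))
  expect_equal(level_invariance_anova(d0)$statistic, 0, tolerance = 1e-12)
  d <- tibble::tibble(delta_tau_us = c(1, 2, 3, 4, 5, 6),
                      level_db_spl = rep(c(50, 60), each = 3))
  a <- level_invariance_anova(d)
  expect_equal(a$statistic, 13.5, tolerance = 1e-12)  # SSB 13.5 / (SSW 4 / 4)
  expect_equal(a$df_between, 1)
  expect_equal(a$df_within, 4)
  shifted <- dplyr::mutate(d, delta_tau_us = delta_tau_us + 100)
  expect_equal(level_invariance_anova(shifted)$statistic, 13.5, tolerance = 1e-10)
  expect_error(level_invariance_anova(d[1:3, ]), "two groups")
})

test_that("two-group t test matches the pooled-variance oracle", {
  cmp <- compare_latency_groups(c(1, 2, 3), c(2, 3, 4))
  # pooled sp = 1, SE = sqrt(2/3), t = -1/0.8165
  expect_equal(cmp$t, -1 / sqrt(2 / 3), tolerance = 1e-6)
  expect_equal(cmp$df, 4)
  expect_equal(compare_latency_groups(c(1, 2, 3), c(1, 2, 3))$t, 0)
  w <- compare_latency_groups(c(1, 2, 3), c(2, 3, 4), var_equal = FALSE)
  expect_equal(w$method, "welch")
  expect_error(compare_latency_groups(1, c(1, 2)), "two values")
})

test_that("latency estimates show no level effect on synthetic cohorts", {
  set.seed(202)
  p <- cochlea_params("gerbil")
  ps <- replicate(100, {
    seed <- sample.int(1e6, 1)
    coh <- make_cohort(p, 4, c(50, 60, 70, 80), seed = seed)
    level_invariance_anova(latency_by_record(coh$spectra))$p_value
  })
  expect_gte(mean(ps > 0.05), 0.95)
})

test_that("gerbil and mouse cohorts separate at p < 0.01", {
  # study-sized cohorts; Welch variant, since the species variances differ
  set.seed(303)
  pg <- cochlea_params("gerbil")
  pm <- cochlea_params("mouse")
  ps <- replicate(100, {
    seed <- sample.int(1e6, 1)
    eg <- latency_by_record(
      make_cohort(pg, 7, c(50, 60, 70, 80), seed = seed)$spectra)
    em <- latency_by_record(make_cohort(pm, 5, 70, seed = seed + 1)$spectra)
    compare_latency_groups(eg, em, var_equal = FALSE)$p_value
  })
  expect_gte(mean(ps < 0.01), 0.95)
})
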