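#' Phase difference between reticular lamina and basilar membrane
#'
#' Convenience wrapper for [transfer_ratio()] with numerator RL and
#' denominator BM: \eqn{\Delta\phi = \phi_{RL} - \phi_{BM}} in cycles per
#' frequency. Since phase lag \eqn{\phi = 2\pi f \tau} grows linearly with
#' frequency for a pure latency \eqn{\tau}, the slope of this curve carries
#' the RL-BM latency difference.
#'
#' @inheritParams transfer_ratio
#' @return See [transfer_ratio()].
#' @export
phase_difference_curve <- function(spectra) {
  transfer_ratio(spectra, "RL", "BM")
}

#' Latency difference from the slope of a phase-difference curve
#'
#' Fits ordinary least squares of \eqn{\Delta\phi} (cycles) on frequency (Hz)
#' over `[fmin_hz, fmax_hz]`, using points flagged above noise. With phase in
#' cycles the latency difference is simply the negated slope:
#' `delta_tau_s = -slope`; positive values mean the reticular lamina phase
#' falls faster with frequency, i.e. the RL vibrates later than the BM.
#'
#' @param curve One record's phase-difference tibble (one animal, one level),
#'   as returned by [phase_difference_curve()], or any data frame with
#'   `frequency_hz` and `phase_diff_cycles` (and optionally `above_noise`).
#' @param fmin_hz,fmax_hz Frequency range of the regression (required; the
#'   conventional default used by the pipeline wrappers is `[0.1 * BF, BF]`).
#' @return Object of class `latency_fit` with elements `delta_tau_s`,
#'   `slope_cycles_per_hz`, `intercept_cycles`, `fit_fmin_hz`, `fit_fmax_hz`,
#'   `n_points`, `r_squared`, `model` (the underlying `lm`), and `data`.
#'   Use [tidy()]/[glance()] to extract tibbles.
#' @export
#' @examples
#' f <- seq(2000, 26000, by = 2000)
#' curve <- tibble::tibble(frequency_hz = f,
#'                         phase_diff_cycles = 0.5 - 1.79e-5 * f)
#' fit <- latency_from_phase_slope(curve, 2000, 26000)
#' fit$delta_tau_s * 1e6  # 17.9 microseconds
latency_from_phase_slope <- function(curve, fmin_hz, fmax_hz) {
  if (missing(fmin_hz) || missing(fmax_hz)) {
    abort("fmin_hz and fmax_hz are required (no implicit fit range)")
  }
  if (!all(c("frequency_hz", "phase_diff_cycles") %in% names(curve))) {
    abort("curve needs columns frequency_hz and phase_diff_cycles")
  }
  keep <- curve$frequency_hz >= fmin_hz & curve$frequency_hz <= fmax_hz
  if ("above_noise" %in% names(curve)) keep <- keep & curve$above_noise
  d <- curve[keep & !is.na(curve$phase_diff_cycles), , drop = FALSE]
  if (nrow(d) < 3) abort("fewer than 3 usable points in the fit range")
  if (diff(range(d$frequency_hz)) == 0) abort("zero frequency spread in the fit range")
  fit <- lm(phase_diff_cycles ~ frequency_hz, data = d)
  slope <- unname(coef(fit)[2L])
  smry <- suppressWarnings(summary(fit))  # noise-free inputs fit exactly
  structure(
    list(
      delta_tau_s = -slope,
      slope_cycles_per_hz = slope,
      intercept_cycles = unname(coef(fit)[1L]),
      fit_fmin_hz = fmin_hz,
      fit_fmax_hz = fmax_hz,
      n_points = nrow(d),
      r_squared = smry$r.squared,
      model = fit,
      data = as_tibble(d)
    ),
    class = "latency_fit"
  )
}

#' @export
print.latency_fit <- function(x, ...) {
  cat(sprintf(
    "<latency_fit> delta_tau = %.2f us over [%.0f, %.0f] Hz (n = %d, R^2 = %.3f)\n",
    x$delta_tau_s * 1e6, x$fit_fmin_hz, x$fit_fmax_hz, x$n_points, x$r_squared
  ))
  invisible(x)
}

#' @export
tidy.latency_fit <- function(x, ...) {
  tibble(
    term = c("intercept_cycles", "slope_cycles_per_hz"),
    estimate = c(x$intercept_cycles, x$slope_cycles_per_hz),
    std.error = unname(suppressWarnings(summary(x$model))$coefficients[, "Std. Error"])
  )
}

#' @export
glance.latency_fit <- function(x, ...) {
  tibble(
    delta_tau_s = x$delta_tau_s,
    delta_tau_us = x$delta_tau_s * 1e6,
    r_squared = x$r_squared,
    n_points = x$n_points,
    fit_fmin_hz = x$fit_fmin_hz,
    fit_fmax_hz = x$fit_fmax_hz
  )
}

#' Per-record latency estimates for a whole cohort
#'
#' Runs the phase-slope pipeline for every animal x state x level record in a
#' spectra table: computes \eqn{\Delta\phi(f)} (RL minus BM), determines each
#' animal's best frequency from its BM spectrum at the lowest level present,
#' and fits over `[fmin_frac * BF, fmax_frac * BF]` (explicit `fmin_hz` /
#' `fmax_hz` override the BF-relative range).
#'
#' @param spectra Spectra table containing RL and BM rows.
#' @param fmin_frac,fmax_frac Fit range as fractions of each animal's BF
#'   (defaults 0.1 and 1).
#' @param fmin_hz,fmax_hz Optional absolute range overriding the fractions.
#' @return Tibble with one row per record: keys, `bf_hz`, `delta_tau_s`,
#'   `delta_tau_us`, `slope_cycles_per_hz`, `intercept_cycles`, `n_points`,
#'   `r_squared`.
#' @export
latency_by_record <- function(spectra, fmin_frac = 0.1, fmax_frac = 1,
                              fmin_hz = NULL, fmax_hz = NULL) {
  spectra <- validate_spectra(spectra)
  curves <- phase_difference_curve(spectra)
  bm <- dplyr::filter(spectra, .data$structure == "BM")
  bf_tbl <- bm |>
    dplyr::group_by(.data$animal_id, .data$species, .data$state) |>
    dplyr::filter(.data$level_db_spl == min(.data$level_db_spl)) |>
    dplyr::ungroup() |>
    best_frequency() |>
    dplyr::select("animal_id", "species", "state", "bf_hz")
  keys <- setdiff(spectrum_keys, "structure")
  curves |>
    dplyr::left_join(bf_tbl, by = c("animal_id", "species", "state")) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(keys, "bf_hz")))) |>
    dplyr::group_modify(function(d, k) {
      lo <- fmin_hz %||% (fmin_frac * k$bf_hz)
      hi <- fmax_hz %||% (fmax_frac * k$bf_hz)
      glance(latency_from_phase_slope(d, lo, hi)) |>
        dplyr::select(-"fit_fmin_hz", -"fit_fmax_hz") |>
        dplyr::mutate(fit_fmin_hz = lo, fit_fmax_hz = hi)
    }) |>
    dplyr::ungroup()
}

#' Grouped latency statistics
#'
#' Mean, standard error of the mean and count of per-record latency
#' estimates. Each animal x level record is treated as an independent
#' observation, so a 7-animal, 4-level cohort contributes n = 28.
#'
#' @param estimates Data frame of per-record estimates (e.g. from
#'   [latency_by_record()]) or a numeric vector.
#' @param value Column holding the estimates (default `delta_tau_us`).
#' @param unit Unit label stored in the result.
#' @return One-row tibble: `mean`, `sem` (`sd/sqrt(n)`; 0 for n = 1), `n`,
#'   `unit`.
#' @export
#' @examples
#' group_latency(c(10, 20, 30))
group_latency <- function(estimates, value = "delta_tau_us", unit = "us") {
  x <- if (is.numeric(estimates)) estimates else estimates[[value]]
  x <- x[!is.na(x)]
  if (length(x) == 0) abort("no estimates to group")
  n <- length(x)
  tibble(
    mean = mean(x),
    sem = if (n > 1) sd(x) / sqrt(n) else 0,
    n = n,
    unit = unit
  )
}

#' One-way ANOVA for level invariance of the latency difference
#'
#' Tests whether per-record latency estimates differ across sound levels with
#' a fixed-effects one-way ANOVA (F with k-1 and N-k degrees of freedom). A
#' large p-value supports pooling estimates across levels.
#'
#' @param estimates Data frame of per-record estimates.
#' @param value Column of estimates (default `delta_tau_us`).
#' @param group Grouping column (default `level_db_spl`).
#' @return One-row tibble: `statistic` (F), `p_value`, `df_between`,
#'   `df_within`, `n_groups`.
#' @export
level_invariance_anova <- function(estimates, value = "delta_tau_us",
                                   group = "level_db_spl") {
  x <- estimates[[value]]
  g <- factor(estimates[[group]])
  ok <- !is.na(x) & !is.na(g)
  x <- x[ok]; g <- droplevels(g[ok])
  if (nlevels(g) < 2) abort("need at least two groups")
  if (any(table(g) < 2)) abort("each group needs at least two values")
  res <- oneway.test(x ~ g, var.equal = TRUE)
  tibble(
    statistic = unname(res$statistic),
    p_value = unname(res$p.value),
    df_between = unname(res$parameter[1L]),
    df_within = unname(res$parameter[2L]),
    n_groups = nlevels(g)
  )
}

#' Two-group comparison of latency estimates
#'
#' Two-sample t test on raw per-record estimates, e.g. gerbil versus mouse
#' cohorts. The default is the Student (pooled-variance) test with
#' `df = n_a + n_b - 2`; set `var_equal = FALSE` for the Welch variant. Both
#' are reported because printed test statistics in the literature do not
#' always identify the variant used.
#'
#' @param a,b Data frames of per-record estimates, or numeric vectors.
#' @param value Column of estimates (default `delta_tau_us`).
#' @param var_equal Pooled variance (TRUE, default) or Welch.
#' @return One-row tibble: `t`, `p_value` (two-sided), `df`, `mean_a`,
#'   `mean_b`, `n_a`, `n_b`, `method`.
#' @export
#' @examples
#' compare_latency_groups(c(1, 2, 3), c(2, 3, 4))
compare_latency_groups <- function(a, b, value = "delta_tau_us",
                                   var_equal = TRUE) {
  xa <- if (is.numeric(a)) a else a[[value]]
  xb <- if (is.numeric(b)) b else b[[value]]
  xa <- xa[!is.na(xa)]; xb <- xb[!is.na(xb)]
  if (length(xa) < 2 || length(xb) < 2) abort("each group needs at least two values")
  res <- t.test(xa, xb, var.equal = var_equal)
  tibble(
    t = unname(res$statistic),
    p_value = unname(res$p.value),
    df = unname(res$parameter),
    mean_a = mean(xa),
    mean_b = mean(xb),
    n_a = length(xa),
    n_b = length(xb),
    method = if (var_equal) "student_pooled" else "welch"
  )
}
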