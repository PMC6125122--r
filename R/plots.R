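#' Plot magnitude and phase of vibration spectra
#'
#' Displacement magnitude (log scale) and unwrapped phase as functions of
#' frequency, coloured by structure, one panel row per quantity, faceted by
#' sound level.
#'
#' @param spectra Spectra table.
#' @return A ggplot object.
#' @export
plot_spectra <- function(spectra) {
  spectra <- validate_spectra(spectra)
  long <- dplyr::bind_rows(
    dplyr::mutate(spectra, what = "magnitude (nm)", y = .data$magnitude_nm),
    dplyr::mutate(spectra, what = "phase (cycles)", y = .data$phase_cycles)
  )
  ggplot2::ggplot(long, ggplot2::aes(
    .data$frequency_hz / 1000, .data$y,
    colour = .data$structure, linetype = .data$state,
    group = interaction(.data$animal_id, .data$structure, .data$state)
  )) +
    ggplot2::geom_line() +
    ggplot2::facet_grid(
      rows = ggplot2::vars(.data$what),
      cols = ggplot2::vars(.data$level_db_spl),
      scales = "free_y"
    ) +
    ggplot2::scale_y_continuous() +
    ggplot2::labs(x = "frequency (kHz)", y = NULL, colour = "structure") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.latency_fit <- function(object, ...) {
  d <- object$data
  ggplot2::ggplot(d, ggplot2::aes(.data$frequency_hz / 1000, .data$phase_diff_cycles)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_abline(
      intercept = object$intercept_cycles,
      slope = object$slope_cycles_per_hz * 1000, linetype = 2
    ) +
    ggplot2::labs(
      x = "frequency (kHz)", y = expression(Delta * phi ~ "(cycles)"),
      title = sprintf("RL-BM latency difference: %.1f µs (R² = %.3f)",
                      object$delta_tau_s * 1e6, object$r_squared)
    ) +
    ggplot2::theme_minimal()
}

#' Plot a click-evoked RL/BM waveform pair
#'
#' @param clicks Time-series table (typically one animal at one level).
#' @param features Optional feature table from [click_features()]; detected
#'   first peaks are marked.
#' @return A ggplot object.
#' @export
plot_click_pair <- function(clicks, features = NULL) {
  clicks <- validate_timeseries(clicks)
  g <- ggplot2::ggplot(clicks, ggplot2::aes(
    .data$time_s * 1000, .data$displacement_nm, colour = .data$structure
  )) +
    ggplot2::geom_line() +
    ggplot2::facet_grid(
      rows = ggplot2::vars(.data$structure),
      cols = ggplot2::vars(.data$level_db_p), scales = "free_y"
    ) +
    ggplot2::labs(x = "time (ms)", y = "displacement (nm)") +
    ggplot2::theme_minimal()
  if (!is.null(features)) {
    g <- g + ggplot2::geom_vline(
      data = features,
      ggplot2::aes(xintercept = .data$first_peak_time_s * 1000),
      linetype = 3
    )
  }
  g
}

#' Plot longitudinal snapshot waveforms
#'
#' Displacement versus cochlear place at one or more instants, as produced by
#' [snapshot_waveform()].
#'
#' @param snapshots Tibble from [snapshot_waveform()].
#' @return A ggplot object.
#' @export
plot_snapshots <- function(snapshots) {
  ggplot2::ggplot(snapshots, ggplot2::aes(
    .data$x_mm, .data$displacement_nm,
    colour = factor(round(.data$t_s * 1e6, 2))
  )) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "distance from base (mm)", y = "displacement (nm)",
                  colour = "t (µs)") +
    ggplot2::theme_minimal()
}
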