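#' Read and write the spectrum TSV dialect
#'
#' One row per frequency, tab-separated with header, UTF-8, '.' decimal:
#' `animal_id species state structure level_db_spl frequency_hz magnitude_nm
#' phase_cycles noise_floor_nm`. On read, rows are sorted by frequency within
#' each record and validated ([validate_spectra()]); if a logical `wrapped`
#' column is present and TRUE for a record, its phase is unwrapped on load.
#'
#' @param path File path.
#' @param spectra Spectra table to write.
#' @return `read_spectra()`: validated tibble. `write_spectra()`: the input,
#'   invisibly.
#' @export
read_spectra <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  missing <- setdiff(spectrum_cols[1:8], names(df))
  if (length(missing) > 0) {
    abort(paste0("spectrum file lacks column(s): ", paste(missing, collapse = ", ")))
  }
  dup <- df |>
    dplyr::count(dplyr::across(dplyr::all_of(c(spectrum_keys, "frequency_hz")))) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0) {
    abort(paste0("duplicate (record, frequency) rows, e.g. ",
                 paste(unlist(dup[1, 1:6]), collapse = "/")))
  }
  df <- df |>
    dplyr::arrange(dplyr::across(dplyr::all_of(c(spectrum_keys, "frequency_hz"))))
  if ("wrapped" %in% names(df)) {
    df <- df |>
      dplyr::group_by(dplyr::across(dplyr::all_of(spectrum_keys))) |>
      dplyr::mutate(phase_cycles = if (isTRUE(.data$wrapped[1L])) {
        unwrap_phase(.data$phase_cycles)
      } else {
        .data$phase_cycles
      }) |>
      dplyr::ungroup() |>
      dplyr::select(-"wrapped")
    }
  validate_spectra(df)
}

#' @rdname read_spectra
#' @export
write_spectra <- function(spectra, path) {
  spectra <- validate_spectra(spectra)
  readr::write_tsv(spectra[, spectrum_cols], path, progress = FALSE)
  invisible(spectra)
}

#' Read and write the click time-series TSV dialect
#'
#' One row per sample: `animal_id species state structure level_db_p time_s
#' displacement_nm`. Uniform sampling is enforced on read.
#'
#' @param path File path.
#' @param clicks Time-series table to write.
#' @return `read_timeseries()`: validated tibble. `write_timeseries()`: the
#'   input, invisibly.
#' @export
read_timeseries <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  missing <- setdiff(timeseries_cols, names(df))
  if (length(missing) > 0) {
    abort(paste0("time-series file lacks column(s): ", paste(missing, collapse = ", ")))
  }
  df <- df |>
    dplyr::arrange(dplyr::across(dplyr::all_of(c(timeseries_keys, "time_s"))))
  validate_timeseries(df)
}

#' @rdname read_timeseries
#' @export
write_timeseries <- function(clicks, path) {
  clicks <- validate_timeseries(clicks)
  readr::write_tsv(clicks[, timeseries_cols], path, progress = FALSE)
  invisible(clicks)
}

#' Summary report of a vibrometry dataset
#'
#' Runs the main analyses available for the supplied data and returns one
#' tidy table of headline quantities: grouped tone latency difference
#' (phase-slope pipeline), its level-invariance ANOVA, RL/BM ratio at BF per
#' level, BM and RL compression between the extreme levels, and grouped
#' click latency difference with first-peak polarities.
#'
#' @param spectra Spectra table (RL and BM required), or NULL.
#' @param clicks Time-series table, or NULL.
#' @param fmin_frac,fmax_frac Phase-fit range as fractions of BF.
#' @return Tibble with columns `quantity`, `value`, `unit`, `n`; analyses
#'   whose inputs are absent are skipped with a warning.
#' @export
vibrometry_report <- function(spectra = NULL, clicks = NULL,
                              fmin_frac = 0.1, fmax_frac = 1) {
  rows <- list()
  if (!is.null(spectra) && nrow(spectra) > 0) {
    spectra <- validate_spectra(spectra)
    est <- latency_by_record(spectra, fmin_frac, fmax_frac)
    sen <- dplyr::filter(est, .data$state == "sensitive")
    if (nrow(sen) > 0) {
      g <- group_latency(sen)
      rows <- c(rows, list(
        tibble(quantity = "tone_delta_tau_mean", value = g$mean, unit = "us", n = g$n),
        tibble(quantity = "tone_delta_tau_sem", value = g$sem, unit = "us", n = g$n)
      ))
      if (length(unique(sen$level_db_spl)) >= 2 && all(table(sen$level_db_spl) >= 2)) {
        a <- level_invariance_anova(sen)
        rows <- c(rows, list(
          tibble(quantity = "level_anova_F", value = a$statistic, unit = "", n = nrow(sen)),
          tibble(quantity = "level_anova_p", value = a$p_value, unit = "", n = nrow(sen))
        ))
      }
      # RL/BM ratio at each animal's BF, averaged per level
      tr <- transfer_ratio(dplyr::filter(spectra, .data$state == "sensitive"), "RL", "BM")
      bf <- dplyr::select(sen, "animal_id", "bf_hz")
      at_bf <- tr |>
        dplyr::inner_join(dplyr::distinct(bf), by = "animal_id") |>
        dplyr::group_by(.data$animal_id, .data$level_db_spl) |>
        dplyr::slice_min(abs(.data$frequency_hz - .data$bf_hz), n = 1, with_ties = FALSE) |>
        dplyr::ungroup()
      per_level <- at_bf |>
        dplyr::group_by(.data$level_db_spl) |>
        dplyr::summarise(value = mean(.data$ratio), n = dplyr::n(), .groups = "drop")
      rows <- c(rows, list(tibble(
        quantity = paste0("rl_bm_ratio_at_bf_", per_level$level_db_spl, "db"),
        value = per_level$value, unit = "", n = per_level$n
      )))
      lvls <- sort(unique(at_bf$level_db_spl))
      if (length(lvls) >= 2) {
        lo <- lvls[1]; hi <- lvls[length(lvls)]
        comp <- at_bf |>
          dplyr::select("animal_id", "level_db_spl", "frequency_hz") |>
          dplyr::inner_join(spectra, by = c("animal_id", "level_db_spl", "frequency_hz"),
                            relationship = "many-to-many") |>
          dplyr::filter(.data$structure %in% c("RL", "BM"), .data$state == "sensitive",
                        .data$level_db_spl %in% c(lo, hi)) |>
          dplyr::group_by(.data$animal_id, .data$structure, .data$level_db_spl) |>
          dplyr::summarise(mag = mean(.data$magnitude_nm), .groups = "drop") |>
          tidyr::pivot_wider(names_from = "level_db_spl", values_from = "mag",
                             names_prefix = "l") |>
          dplyr::mutate(comp_db = compression_db(lo, hi,
            .data[[paste0("l", hi)]] / .data[[paste0("l", lo)]])) |>
          dplyr::group_by(.data$structure) |>
          dplyr::summarise(value = mean(.data$comp_db), n = dplyr::n(), .groups = "drop")
        rows <- c(rows, list(tibble(
          quantity = paste0(tolower(comp$structure), "_compression_", lo, "_", hi, "db"),
          value = comp$value, unit = "dB", n = comp$n
        )))
      }
    }
  } else {
    warn("no spectra supplied; tone analyses skipped")
  }
  if (!is.null(clicks) && nrow(clicks) > 0) {
    lat <- click_latency_difference(click_features(clicks)) |>
      dplyr::filter(.data$state == "sensitive")
    if (nrow(lat) > 0) {
      g <- group_latency(lat)
      rows <- c(rows, list(
        tibble(quantity = "click_delta_tau_mean", value = g$mean, unit = "us", n = g$n),
        tibble(quantity = "click_delta_tau_sem", value = g$sem, unit = "us", n = g$n),
        tibble(quantity = "click_peak_ratio_mean", value = mean(lat$peak_ratio),
               unit = "", n = nrow(lat))
      ))
    }
  }
  if (length(rows) == 0) {
    warn("empty dataset: nothing to report")
    return(tibble(quantity = character(), value = numeric(),
                  unit = character(), n = integer()))
  }
  dplyr::bind_rows(rows)
}
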