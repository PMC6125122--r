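#' Validate a table of tone-evoked vibration spectra
#'
#' A spectra table holds one row per stimulus frequency, keyed by
#' `animal_id`, `species`, `state` (sensitive/postmortem), `structure`
#' (RL, BM, stapes, OHC) and `level_db_spl`. Within each key the frequency
#' grid must be strictly increasing and positive, magnitudes non-negative and
#' the stored phase unwrapped (no adjacent jump larger than half a cycle).
#'
#' @param spectra Data frame in the spectrum dialect (see [read_spectra()]).
#' @param unwrapped Check the no-jump-\eqn{>0.5}-cycles invariant (default TRUE).
#' @return The input as a tibble, invisibly usable in a pipe; errors describe
#'   the first offending group.
#' @export
validate_spectra <- function(spectra, unwrapped = TRUE) {
  spectra <- as_tibble(spectra)
  missing <- setdiff(spectrum_cols[1:8], names(spectra))
  if (length(missing) > 0) {
    abort(paste0("spectra table lacks column(s): ", paste(missing, collapse = ", ")))
  }
  if (!"noise_floor_nm" %in% names(spectra)) {
    spectra$noise_floor_nm <- NA_real_
  }
  check_group <- function(df, key) {
    f <- df$frequency_hz
    if (any(f <= 0)) abort(paste0("non-positive frequency in group ", key))
    if (is.unsorted(f, strictly = TRUE)) {
      abort(paste0("frequency grid not strictly increasing in group ", key))
    }
    if (any(df$magnitude_nm < 0)) abort(paste0("negative magnitude in group ", key))
    if (unwrapped && length(f) > 1 && any(abs(diff(df$phase_cycles)) > 0.5)) {
      abort(paste0("phase not unwrapped (adjacent jump > 0.5 cycles) in group ", key))
    }
    invisible(NULL)
  }
  grp <- dplyr::group_by(spectra, dplyr::across(dplyr::all_of(spectrum_keys)))
  keys <- dplyr::group_keys(grp)
  dfs <- dplyr::group_split(grp)
  for (i in seq_along(dfs)) {
    check_group(dfs[[i]], paste(unlist(keys[i, ]), collapse = "/"))
  }
  spectra
}

#' Per-frequency ratio of two structures' vibration
#'
#' Forms, for every animal/state/level present for both structures, the
#' magnitude ratio |numerator|/|denominator| and the phase difference
#' \eqn{\Delta\phi = \phi_{num} - \phi_{den}} (cycles, both inputs already
#' unwrapped). This is the transfer-function estimate when the denominator is
#' the stapes, and the RL/BM comparison when it is the basilar membrane.
#'
#' Points where either input sits at or below its noise floor are kept but
#' flagged `above_noise = FALSE`; downstream ratio and phase statistics
#' exclude flagged points. A zero denominator magnitude yields `ratio = NA`
#' with `above_noise = FALSE` (undefined ratio).
#'
#' @param spectra Spectra table containing both structures on identical
#'   frequency grids per key.
#' @param numerator,denominator Structure labels, e.g. `"RL"`, `"BM"`,
#'   `"stapes"`.
#' @return Tibble with columns `animal_id`, `species`, `state`,
#'   `level_db_spl`, `numerator`, `denominator`, `frequency_hz`, `ratio`,
#'   `phase_diff_cycles`, `above_noise`.
#' @export
#' @examples
#' coh <- make_spectra(cochlea_params("gerbil"), "g1", 30, noise = FALSE)
#' transfer_ratio(coh, "RL", "BM")
transfer_ratio <- function(spectra, numerator, denominator) {
  spectra <- validate_spectra(spectra)
  num <- dplyr::filter(spectra, .data$structure == numerator)
  den <- dplyr::filter(spectra, .data$structure == denominator)
  if (nrow(num) == 0 || nrow(den) == 0) {
    abort(paste0("structure(s) not found: need both '", numerator, "' and '", denominator, "'"))
  }
  keys <- setdiff(spectrum_keys, "structure")
  joined <- dplyr::inner_join(
    num, den,
    by = c(keys, "frequency_hz"), suffix = c("_num", "_den")
  )
  # identical grids required: every row of each side must pair up
  n_expected <- length(unique(paste(joined$animal_id, joined$state, joined$level_db_spl)))
  by_key_num <- dplyr::count(num, dplyr::across(dplyr::all_of(keys)))
  by_key_join <- dplyr::count(joined, dplyr::across(dplyr::all_of(keys)))
  chk <- dplyr::inner_join(by_key_num, by_key_join, by = keys, suffix = c("_num", "_join"))
  if (nrow(chk) == 0 || any(chk$n_num != chk$n_join)) {
    abort("frequency grids of numerator and denominator do not match")
  }
  joined |>
    dplyr::mutate(
      numerator = numerator,
      denominator = denominator,
      ratio = dplyr::if_else(.data$magnitude_nm_den > 0,
        .data$magnitude_nm_num / .data$magnitude_nm_den, NA_real_
      ),
      phase_diff_cycles = .data$phase_cycles_num - .data$phase_cycles_den,
      above_noise =
        .data$magnitude_nm_den > 0 &
          (is.na(.data$noise_floor_nm_num) | .data$magnitude_nm_num > .data$noise_floor_nm_num) &
          (is.na(.data$noise_floor_nm_den) | .data$magnitude_nm_den > .data$noise_floor_nm_den)
    ) |>
    dplyr::select(dplyr::all_of(c(
      keys, "numerator", "denominator", "frequency_hz",
      "ratio", "phase_diff_cycles", "above_noise"
    ))) |>
    dplyr::arrange(dplyr::across(dplyr::all_of(c(keys, "frequency_hz"))))
}

#' Nonlinear compression of response growth, in dB
#'
#' Compression is the shortfall of response growth relative to stimulus
#' growth: `(level_hi - level_lo) - 20 * log10(displacement_fold)` dB, where
#' `displacement_fold` is the factor by which displacement grew over the same
#' level step. Zero for proportional (linear) growth; equal to the level step
#' for complete saturation.
#'
#' @param level_lo_db,level_hi_db Sound levels in dB SPL, `level_hi_db`
#'   strictly greater.
#' @param displacement_fold Positive fold-change of displacement from the low
#'   to the high level.
#' @return Compression in dB (vectorised).
#' @export
#' @examples
#' compression_db(30, 80, 3.3)  # ~40 dB, strong compression
#' compression_db(30, 80, 23)   # ~23 dB
compression_db <- function(level_lo_db, level_hi_db, displacement_fold) {
  if (any(!is.finite(level_lo_db)) || any(!is.finite(level_hi_db))) {
    abort("sound levels must be finite")
  }
  if (any(level_hi_db <= level_lo_db)) {
    abort("level_hi_db must exceed level_lo_db")
  }
  if (any(!is.finite(displacement_fold)) || any(displacement_fold <= 0)) {
    abort("displacement_fold must be positive")
  }
  (level_hi_db - level_lo_db) - 20 * log10(displacement_fold)
}

#' Best frequency of each spectrum
#'
#' The best frequency (BF) is the grid frequency at which displacement
#' magnitude peaks; by convention it is read from the basilar-membrane
#' response at the lowest sound level available. Ties are broken toward the
#' lowest frequency, deterministically.
#'
#' @param spectra Spectra table; BF is computed per
#'   animal/species/state/structure/level group.
#' @return Tibble of the group keys plus `bf_hz` and `bf_magnitude_nm`.
#' @export
best_frequency <- function(spectra) {
  spectra <- validate_spectra(spectra)
  one <- function(df) {
    if (nrow(df) < 3) abort("best_frequency needs at least 3 frequencies")
    m <- df$magnitude_nm
    if (diff(range(m)) == 0) abort("no peak: all magnitudes equal")
    i <- which(m == max(m))[1L]  # tie -> lowest frequency (rows sorted)
    tibble(bf_hz = df$frequency_hz[i], bf_magnitude_nm = m[i])
  }
  spectra |>
    dplyr::group_by(dplyr::across(dplyr::all_of(spectrum_keys))) |>
    dplyr::arrange(.data$frequency_hz, .by_group = TRUE) |>
    dplyr::group_modify(~ one(.x)) |>
    dplyr::ungroup()
}

#' DPOAE sensitivity check
#'
#' Cochlear condition is monitored by the distortion-product otoacoustic
#' emission (DPOAE) level before and after a measurement; a preparation whose
#' DPOAE dropped by less than 5 dB is classed sensitive.
#'
#' @param pre_db,post_db DPOAE levels (dB SPL) before/after; vectorised.
#' @return Tibble with `dpoae_pre_db`, `dpoae_post_db`, `drop_db`
#'   (`pre - post`) and logical `sensitive` (`drop_db < 5`).
#' @export
#' @examples
#' dpoae_qc(20, 16)  # 4 dB drop: still sensitive
dpoae_qc <- function(pre_db, post_db) {
  if (any(!is.finite(pre_db)) || any(!is.finite(post_db))) {
    abort("DPOAE levels must be finite dB values")
  }
  drop <- pre_db - post_db
  tibble(
    dpoae_pre_db = pre_db,
    dpoae_post_db = post_db,
    drop_db = drop,
    sensitive = drop < 5
  )
}
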