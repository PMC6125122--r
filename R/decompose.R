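#' Isolate the outer hair cell-driven reticular lamina component
#'
#' The measured reticular lamina vibration is modelled as the sum of a
#' passive component following the basilar membrane and an active component
#' driven by outer hair cells. The active component is obtained by complex
#' vector subtraction per frequency:
#' \deqn{D_{OHC}(f) = D_{RL}(f) - D_{BM}(f)}
#' where each displacement is the phasor `magnitude * exp(i 2 pi phase)`.
#'
#' Subtraction is performed only within matching animal/state/level records
#' (same stimulus, same run); the function refuses to combine across
#' conditions, and errors if the two structures' frequency grids differ.
#' Output phase is unwrapped along frequency, anchored at the lowest
#' frequency.
#'
#' @param spectra Spectra table containing RL and BM rows.
#' @return Tibble in the spectrum dialect with `structure = "OHC"`; the noise
#'   floor is carried over as the elementwise maximum of the two inputs'
#'   floors.
#' @export
#' @examples
#' coh <- make_spectra(cochlea_params("gerbil"), "g1", 30, noise = FALSE)
#' ohc <- subtract_active(coh)
subtract_active <- function(spectra) {
  spectra <- validate_spectra(spectra)
  rl <- dplyr::filter(spectra, .data$structure == "RL")
  bm <- dplyr::filter(spectra, .data$structure == "BM")
  if (nrow(rl) == 0 || nrow(bm) == 0) abort("spectra must contain RL and BM rows")
  keys <- setdiff(spectrum_keys, "structure")
  joined <- dplyr::inner_join(rl, bm,
    by = c(keys, "frequency_hz"), suffix = c("_rl", "_bm")
  )
  if (nrow(joined) != nrow(rl) || nrow(joined) != nrow(bm)) {
    abort("RL and BM frequency grids do not match within records")
  }
  joined |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::arrange(.data$frequency_hz, .by_group = TRUE) |>
    dplyr::group_modify(function(d, k) {
      z <- as_phasor(d$magnitude_nm_rl, d$phase_cycles_rl) -
        as_phasor(d$magnitude_nm_bm, d$phase_cycles_bm)
      mag <- phasor_magnitude(z)
      ph <- phasor_phase_cycles(z)
      ph[mag == 0] <- 0  # phase of a null phasor is indeterminate
      tibble(
        frequency_hz = d$frequency_hz,
        magnitude_nm = mag,
        phase_cycles = unwrap_phase(ph),
        noise_floor_nm = pmax(d$noise_floor_nm_rl, d$noise_floor_nm_bm)
      )
    }) |>
    dplyr::ungroup() |>
    dplyr::mutate(structure = "OHC") |>
    dplyr::select(dplyr::all_of(spectrum_cols))
}

#' Dominance of the active component in reticular lamina motion
#'
#' Per-frequency ratio `|D_OHC| / |D_RL|`: close to 1 where the outer hair
#' cell-driven component dominates the reticular lamina vibration (low sound
#' levels near the best frequency), close to 0 where the RL passively follows
#' the basilar membrane.
#'
#' @param spectra Spectra table containing RL and BM rows.
#' @return Tibble keyed like [transfer_ratio()] with columns `frequency_hz`,
#'   `dominance` and logical `defined` (FALSE where `|D_RL| = 0`).
#' @export
dominance_index <- function(spectra) {
  ohc <- subtract_active(spectra)
  rl <- dplyr::filter(validate_spectra(spectra), .data$structure == "RL")
  keys <- setdiff(spectrum_keys, "structure")
  dplyr::inner_join(ohc, rl,
    by = c(keys, "frequency_hz"), suffix = c("_ohc", "_rl")
  ) |>
    dplyr::mutate(
      dominance = dplyr::if_else(.data$magnitude_nm_rl > 0,
        .data$magnitude_nm_ohc / .data$magnitude_nm_rl, NA_real_
      ),
      defined = .data$magnitude_nm_rl > 0
    ) |>
    dplyr::select(dplyr::all_of(c(keys, "frequency_hz", "dominance", "defined")))
}
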