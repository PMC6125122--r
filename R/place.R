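#' Frequency-to-place map of the cochlea
#'
#' A log-linear percent-distance map
#' \deqn{d\% = a - b \log_{10}(f / 1\,\mathrm{kHz})}
#' converted to millimetres along a basilar membrane of length `bm_length_mm`.
#' With `orientation = "from_base"` (default) distance is measured from the
#' basal end, so place decreases as frequency increases (high frequencies map
#' to the base); `"from_apex"` reports `L - x`.
#'
#' @param a_percent Intercept of the percent-distance map.
#' @param b_percent_per_decade Slope per decade of frequency; must be
#'   positive (monotone map).
#' @param bm_length_mm Basilar membrane length in mm.
#' @param orientation `"from_base"` or `"from_apex"`.
#' @return Object of class `place_map`.
#' @seealso [place_map_gerbil()], [frequency_to_place()]
#' @export
place_map <- function(a_percent, b_percent_per_decade, bm_length_mm,
                      orientation = c("from_base", "from_apex")) {
  orientation <- match.arg(orientation)
  if (b_percent_per_decade <= 0) abort("b_percent_per_decade must be positive")
  if (bm_length_mm <= 0) abort("bm_length_mm must be positive")
  structure(
    list(
      a_percent = a_percent,
      b_percent_per_decade = b_percent_per_decade,
      bm_length_mm = bm_length_mm,
      orientation = orientation
    ),
    class = "place_map"
  )
}

#' @export
print.place_map <- function(x, ...) {
  cat(sprintf(
    "<place_map> d%% = %.2f - %.2f log10(f/kHz), L = %.1f mm, %s\n",
    x$a_percent, x$b_percent_per_decade, x$bm_length_mm, x$orientation
  ))
  invisible(x)
}

#' Gerbil basal-turn place map preset
#'
#' A log-linear approximation of the gerbil frequency-position function for
#' the basal half of the cochlea. The slope is the Greenwood-style
#' 100/2.2 percent per decade and the intercept is calibrated so that
#' 26 kHz maps to 2.05 mm from the base on an 11.1 mm basilar membrane.
#' This is a synthetic calibration of the map's published form, not a
#' transcription of any published constant set; treat results outside
#' roughly 5-40 kHz with caution.
#'
#' @return A [place_map()] object.
#' @export
#' @examples
#' frequency_to_place(26000, place_map_gerbil())  # ~2.05 mm from the base
place_map_gerbil <- function() {
  b <- 100 / 2.2
  a <- 100 * 2.05 / 11.1 + b * log10(26)
  place_map(a, b, 11.1, "from_base")
}

#' Map stimulus frequency to cochlear place
#'
#' @param f_hz Frequencies in Hz; all must fall where the map yields a
#'   percent distance between 0 and 100.
#' @param map A [place_map()].
#' @return Distances in mm per the map's orientation.
#' @export
frequency_to_place <- function(f_hz, map) {
  if (!inherits(map, "place_map")) abort("map must be a place_map")
  d_pct <- map$a_percent - map$b_percent_per_decade * log10(f_hz / 1000)
  if (any(!is.finite(d_pct)) || any(d_pct < 0) || any(d_pct > 100)) {
    abort("frequency outside the valid range of the place map")
  }
  x <- map$bm_length_mm * d_pct / 100
  if (map$orientation == "from_apex") x <- map$bm_length_mm - x
  x
}

#' Inverse place map: cochlear place to frequency
#'
#' @param x_mm Distances in mm (per the map's orientation).
#' @param map A [place_map()].
#' @return Frequencies in Hz.
#' @export
place_to_frequency <- function(x_mm, map) {
  if (!inherits(map, "place_map")) abort("map must be a place_map")
  x <- if (map$orientation == "from_apex") map$bm_length_mm - x_mm else x_mm
  d_pct <- 100 * x / map$bm_length_mm
  if (any(d_pct < 0) || any(d_pct > 100)) abort("place outside the basilar membrane")
  1000 * 10^((map$a_percent - d_pct) / map$b_percent_per_decade)
}

#' Longitudinal vibration profile from a frequency spectrum
#'
#' Re-indexes a tone-evoked spectrum by cochlear place: each stimulus
#' frequency is mapped to its characteristic place, and magnitude and phase
#' become functions of longitudinal position, sorted by increasing distance.
#'
#' @param spectra Spectra table (any number of records).
#' @param map A [place_map()].
#' @return Tibble: record keys plus `x_mm`, `frequency_hz`, `magnitude_nm`,
#'   `phase_cycles`, sorted by `x_mm` within records.
#' @export
spectra_to_place_profile <- function(spectra, map) {
  spectra <- validate_spectra(spectra)
  spectra |>
    dplyr::mutate(x_mm = frequency_to_place(.data$frequency_hz, map)) |>
    dplyr::select(dplyr::all_of(c(
      spectrum_keys, "x_mm", "frequency_hz", "magnitude_nm", "phase_cycles"
    ))) |>
    dplyr::arrange(dplyr::across(dplyr::all_of(c(spectrum_keys, "x_mm"))))
}

#' Instantaneous snapshot of the longitudinal vibration pattern
#'
#' Reconstructs the displacement wave along the cochlea at given instants for
#' a pure tone of frequency `f_hz`:
#' \deqn{W(x; t) = \mathrm{mag}(x)\,\cos(2\pi (f t + \phi(x)))}
#' Phase enters with a plus sign inside the cosine, so a larger phase lag
#' (more negative stored phase) shifts the local waveform later in time.
#' Snapshots separated by a full period `1/f` are identical.
#'
#' @param profile Place profile from [spectra_to_place_profile()] (one
#'   record, or at least one set of unique `x_mm`).
#' @param f_hz Stimulus frequency in Hz.
#' @param t_s Vector of snapshot times in seconds.
#' @return Tibble: `t_s`, `x_mm`, `displacement_nm`.
#' @export
snapshot_waveform <- function(profile, f_hz, t_s) {
  if (nrow(profile) == 0) abort("empty place profile")
  purrr::map_dfr(t_s, function(tt) {
    tibble(
      t_s = tt,
      x_mm = profile$x_mm,
      displacement_nm = profile$magnitude_nm *
        cos(2 * pi * (f_hz * tt + profile$phase_cycles))
    )
  })
}
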