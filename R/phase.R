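#' Wrap phase into the principal interval
#'
#' Maps phase values (in cycles; 1 cycle = 360 degrees) into the half-open
#' interval (-0.5, 0.5]. Used when emulating the raw output of a lock-in
#' amplifier, and as the inverse of [unwrap_phase()] in round-trip checks.
#'
#' @param phase_cycles Numeric vector of phase values in cycles.
#' @return Numeric vector of the same length with values in (-0.5, 0.5].
#' @seealso [unwrap_phase()]
#' @export
#' @examples
#' wrap_phase(c(0.4, 0.55, 0.7))
wrap_phase <- function(phase_cycles) {
  w <- phase_cycles - round(phase_cycles)
  # round() sends x.5 either way; force the boundary to +0.5, not -0.5
  w[w == -0.5] <- 0.5
  w
}

#' Unwrap a wrapped phase sequence
#'
#' Reconstructs a continuous phase curve from values wrapped into
#' (-0.5, 0.5] cycles, assuming the true adjacent steps are smaller than
#' half a cycle. The first element anchors the result, so unwrapping is
#' relative to the lowest frequency; no absolute phase reference is assumed.
#'
#' @param wrapped Numeric vector of wrapped phase values in cycles.
#' @return Numeric vector: `out[1] == wrapped[1]`, adjacent differences lie in
#'   (-0.5, 0.5], and `out` equals `wrapped` modulo 1 elementwise.
#' @export
#' @examples
#' unwrap_phase(c(0.4, -0.45, -0.3))  # 0.4 0.55 0.7
unwrap_phase <- function(wrapped) {
  if (length(wrapped) == 0L) {
    abort("cannot unwrap an empty phase sequence")
  }
  if (anyNA(wrapped)) {
    abort("phase sequence contains missing values")
  }
  steps <- wrap_phase(diff(wrapped))
  cumsum(c(wrapped[1L], steps))
}

#' Convert between cycles and degrees
#'
#' Internally all phases are kept in cycles; these converters live at the
#' boundary for interacting with degree-based figures and instruments.
#'
#' @param cycles,degrees Numeric vectors.
#' @return Numeric vector in the other unit.
#' @export
cycles_to_degrees <- function(cycles) cycles * 360

#' @rdname cycles_to_degrees
#' @export
degrees_to_cycles <- function(degrees) degrees / 360

#' Convert magnitude/phase to complex phasors and back
#'
#' A displacement at one frequency is represented as a phasor
#' `magnitude * exp(i * 2 * pi * phase)`. `as_phasor()` builds the complex
#' vector; `phasor_magnitude()` and `phasor_phase_cycles()` invert it
#' (phase wrapped into (-0.5, 0.5]; unwrap along frequency afterwards).
#'
#' @param magnitude_nm Non-negative magnitudes (nm).
#' @param phase_cycles Phases in cycles.
#' @param z Complex vector.
#' @return `as_phasor()`: complex vector; the inverses: numeric vectors.
#' @export
as_phasor <- function(magnitude_nm, phase_cycles) {
  magnitude_nm * exp(2i * pi * phase_cycles)
}

#' @rdname as_phasor
#' @export
phasor_magnitude <- function(z) Mod(z)

#' @rdname as_phasor
#' @export
phasor_phase_cycles <- function(z) Arg(z) / (2 * pi)
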