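#' Parameters of the synthetic two-component cochlea model
#'
#' The generator emulates the *descriptors* of in-vivo basal-turn vibrometry
#' measurements rather than cochlear biophysics: a compressive, sharply tuned
#' basilar membrane (BM) response with traveling-wave phase; a reticular
#' lamina (RL) response equal to the BM response scaled by a level- and
#' frequency-dependent magnitude ratio and shifted by the phase-difference
#' law \deqn{\Delta\phi(f) = 0.5 - f\,\Delta\tau \quad (cycles),}
#' i.e. half-a-cycle opposition at low frequencies decaying with a fixed
#' delay slope; a flat stapes reference; and a postmortem mode in which the
#' active terms are zeroed and the RL passively follows the BM
#' (`RL = beta_pm * BM * exp(-i 2 pi f delta_pm_s)`).
#'
#' Calibration constants for the gerbil preset: best frequency 26 kHz; RL/BM
#' magnitude ratio at BF of 10 at 30 dB SPL falling (log-level interpolated)
#' to 1.5 at 80 dB SPL, with an extra low-frequency ratio term growing with
#' level; BM compression of 23 dB over 30-80 dB SPL at BF; tone-derived
#' latency difference 17.9 us and click-derived 32.6 us (kept separate: the
#' two stimulus types yield different values); click RL/BM first-peak
#' magnitude ratio 8 at 90 dB-p with opposite first-peak polarities. The
#' mouse preset uses a 48 kHz best frequency and a 12.1 us tone latency
#' difference. Filter shapes, gain laws and noise statistics are plumbing
#' choices documented in the methods vignette.
#'
#' @param species `"gerbil"` or `"mouse"`; selects the preset defaults.
#' @param ... Named overrides of any default listed below.
#' @return Object of class `cochlea_params` (a validated named list).
#' @export
#' @examples
#' p <- cochlea_params("gerbil")
#' p$bf_hz
cochlea_params <- function(species = c("gerbil", "mouse"), ...) {
  species <- match.arg(species)
  defaults <- list(
    species = species,
    # tone stimulus grid (instrument convention: 1.8-40 kHz by 0.2 kHz)
    bf_hz = 26000, f_min_hz = 1800, f_max_hz = 40000, f_step_hz = 200,
    # BM magnitude law
    peak_disp_nm = 0.3,          # BM displacement at BF, 30 dB SPL
    passive_peak_frac = 0.85,    # passive resonance sits below BF
    tune_lo_db_per_oct2 = 2.0,   # broad low side of the passive profile
    tune_hi_db_per_oct2 = 15,    # steep high-side cutoff
    act_db = 30,                 # active gain at BF at 30 dB SPL
    c_bm_db = 23,                # BM compression at BF over 30->80 dB SPL
    comp_width_oct = 0.30,       # width of the active/compressive region
    level_ref_lo_db = 30, level_ref_hi_db = 80,
    # RL/BM magnitude ratio law
    ratio_bf_lo = 10, ratio_bf_hi = 1.5,
    ratio_lf_slope = 1.2,        # decades of extra low-f ratio at 80 dB SPL
    # phase laws
    bm_phase_tau0_s = 100e-6, bm_phase_s_cycles = 1, bm_phase_m = 2,
    delta_tau_tone_s = 17.9e-6,
    delta_tau_click_s = 32.6e-6,
    # stapes reference
    stapes_disp_nm_80db = 0.5, stapes_tau_s = 30e-6,
    # click path
    t_me_s = 365e-6,             # middle-ear + speaker delay
    click_ratio = 8,
    click_q = 4,                 # centre frequency / bandwidth of click filter
    click_order = 2,             # filter order (sharp onset, fast decay)
    click_lf_frac = 0.15,        # weight of the slower low-frequency RL path
    click_lf_center_frac = 0.75, # its centre frequency relative to BF
    click_bm_peak_nm_90 = 2.5,
    click_dur_s = 5e-3, fs_hz = 2e5, click_pulse_s = 10e-6,
    n_averages = 100, click_noise_nm = 0.2,
    # cohort dispersion and noise
    tau_sd_animal_s = 1.5e-6, tau_sd_record_s = 2.6e-6,
    tau_click_sd_s = 4.7e-6,
    bf_jitter_sigma = 0.03,
    sigma_phase_cycles = 0.02, sigma_mag_log10 = 0.05,
    noise_floor_nm = 1e-4,
    # postmortem mode
    beta_pm = 0.7, delta_pm_s = 5e-6
  )
  if (species == "mouse") {
    defaults$bf_hz <- 48000
    defaults$f_max_hz <- 64000
    defaults$delta_tau_tone_s <- 12.1e-6
    defaults$delta_tau_click_s <- 22e-6
    defaults$tau_sd_animal_s <- 1.0e-6
    defaults$tau_sd_record_s <- 0.9e-6
    defaults$tau_click_sd_s <- 3e-6
    defaults$beta_pm <- 0.95
  }
  dots <- list(...)
  unknown <- setdiff(names(dots), names(defaults))
  if (length(unknown) > 0) {
    abort(paste0("unknown parameter(s): ", paste(unknown, collapse = ", ")))
  }
  p <- utils::modifyList(defaults, dots)
  pos <- c(
    "bf_hz", "f_min_hz", "f_max_hz", "f_step_hz", "peak_disp_nm",
    "comp_width_oct", "ratio_bf_lo", "ratio_bf_hi", "click_ratio",
    "click_bm_peak_nm_90", "click_dur_s", "fs_hz", "click_pulse_s",
    "noise_floor_nm", "beta_pm"
  )
  for (nm in pos) {
    if (!is.numeric(p[[nm]]) || p[[nm]] <= 0) abort(paste0(nm, " must be positive"))
  }
  if (p$f_max_hz <= p$f_min_hz) abort("f_max_hz must exceed f_min_hz")
  if (p$bf_hz > p$f_max_hz) abort("bf_hz must lie within the frequency grid")
  structure(p, class = "cochlea_params")
}

#' @export
print.cochlea_params <- function(x, ...) {
  cat(sprintf(
    "<cochlea_params> %s: BF %.1f kHz, tone dtau %.1f us, click dtau %.1f us\n",
    x$species, x$bf_hz / 1000, x$delta_tau_tone_s * 1e6, x$delta_tau_click_s * 1e6
  ))
  invisible(x)
}

# ---- internal magnitude/phase laws ---------------------------------------

octaves <- function(f, f0) log2(f / f0)

# passive (postmortem) magnitude profile in dB, broad peak below BF
passive_db <- function(p, f) {
  fp <- p$passive_peak_frac * p$bf_hz
  o <- octaves(f, fp)
  ifelse(o < 0, -p$tune_lo_db_per_oct2 * o^2, -p$tune_hi_db_per_oct2 * o^2)
}

# activation profile: 1 at BF, ~0 far below/above
act_profile <- function(p, f) {
  exp(-octaves(f, p$bf_hz)^2 / (2 * p$comp_width_oct^2))
}

# active amplitude gain at BF vs level, calibrated so the total BM response
# at BF is compressed by exactly c_bm_db over the reference level span
act_amp <- function(p, level_db) {
  a30 <- 10^(p$act_db / 20)
  span <- p$level_ref_hi_db - p$level_ref_lo_db
  pmax(0, (1 + a30) * 10^(-p$c_bm_db * (level_db - p$level_ref_lo_db) / (span * 20)) - 1)
}

# total BM magnitude (nm): passive amplitude plus an active component near
# BF. The active Gaussian is centred a hair above BF so that, at the
# reference low level, its upward pull exactly cancels the passive
# profile's downward slope at BF: the 30 dB SPL peak then sits at BF and
# drifts below BF as the active gain shrinks with level.
bm_magnitude_nm <- function(p, f, level_db, state = "sensitive") {
  a30 <- 10^(p$act_db / 20)
  sig2 <- p$comp_width_oct^2
  # downward ln-amplitude slope of the passive profile at BF, per octave
  ln_slope <- log(10) / 20 * 2 * p$tune_hi_db_per_oct2 * octaves(p$bf_hz, p$passive_peak_frac * p$bf_hz)
  cshift <- ln_slope * sig2 * (1 + a30) / a30
  o <- octaves(f, p$bf_hz)
  act_shape <- exp(-((o - cshift)^2 - cshift^2) / (2 * sig2))  # = 1 at BF
  act <- if (state == "sensitive") act_amp(p, level_db) * act_shape else 0
  scale <- p$peak_disp_nm / (10^(passive_db(p, p$bf_hz) / 20) * (1 + a30))
  scale * 10^((passive_db(p, f) + (level_db - p$level_ref_lo_db)) / 20) * (1 + act)
}

bm_phase_cycles <- function(p, f) {
  -f * p$bm_phase_tau0_s - p$bm_phase_s_cycles * (f / p$bf_hz)^p$bm_phase_m
}

# RL/BM magnitude ratio law (tone, sensitive state)
ratio_law <- function(p, f, level_db) {
  span <- p$level_ref_hi_db - p$level_ref_lo_db
  frac <- (level_db - p$level_ref_lo_db) / span
  log_rbf <- log10(p$ratio_bf_lo) +
    frac * (log10(p$ratio_bf_hi) - log10(p$ratio_bf_lo))
  h <- p$ratio_lf_slope * pmax(0, level_db - p$level_ref_lo_db) / span
  10^(log_rbf + h * pmax(0, 1 - f / p$bf_hz))
}

#' Phase-difference law of the synthetic model
#'
#' The RL-BM phase difference injected by the generator:
#' `0.5 - f * delta_tau` cycles, with the tone or click delay parameter.
#' Exactly half a cycle (180 degrees) in the low-frequency limit.
#'
#' @param params A [cochlea_params()].
#' @param f_hz Frequencies in Hz.
#' @param stimulus `"tone"` or `"click"` (selects the delay constant).
#' @return Phase difference in cycles.
#' @export
#' @examples
#' 360 * delta_phi_law(cochlea_params("gerbil"), 10)  # ~180 degrees
delta_phi_law <- function(params, f_hz, stimulus = c("tone", "click")) {
  stimulus <- match.arg(stimulus)
  tau <- switch(stimulus,
    tone = params$delta_tau_tone_s,
    click = params$delta_tau_click_s
  )
  0.5 - f_hz * tau
}

#' Synthesise tone-evoked RL, BM and stapes spectra
#'
#' Generates one animal/level record of the synthetic model in the spectrum
#' dialect. Deterministic for `noise = FALSE`; with noise, draws from the
#' current RNG state (seed management belongs to [make_cohort()] or the
#' caller).
#'
#' @param params A [cochlea_params()].
#' @param animal_id Label for the record.
#' @param level_db_spl Sound level in dB SPL.
#' @param state `"sensitive"` or `"postmortem"`.
#' @param noise Apply multiplicative magnitude noise and additive phase
#'   noise (default TRUE).
#' @param delta_tau_s Optional override of the tone latency difference for
#'   this record (used for per-animal/per-record jitter).
#' @return Spectra tibble with RL, BM and stapes rows.
#' @export
make_spectra <- function(params, animal_id, level_db_spl,
                         state = c("sensitive", "postmortem"),
                         noise = TRUE, delta_tau_s = NULL) {
  if (!inherits(params, "cochlea_params")) abort("params must be cochlea_params")
  state <- match.arg(state)
  p <- params
  tau <- delta_tau_s %||% p$delta_tau_tone_s
  f <- seq(p$f_min_hz, p$f_max_hz, by = p$f_step_hz)

  bm_mag <- bm_magnitude_nm(p, f, level_db_spl, state)
  bm_ph <- bm_phase_cycles(p, f)
  if (state == "sensitive") {
    rl_mag <- bm_mag * ratio_law(p, f, level_db_spl)
    rl_ph <- bm_ph + 0.5 - f * tau
  } else {
    rl_mag <- p$beta_pm * bm_mag
    rl_ph <- bm_ph - f * p$delta_pm_s
  }
  st_mag <- rep(p$stapes_disp_nm_80db * 10^((level_db_spl - 80) / 20), length(f))
  st_ph <- -f * p$stapes_tau_s

  one <- function(structure, mag, ph) {
    if (noise) {
      mag <- mag * 10^rnorm(length(mag), 0, p$sigma_mag_log10)
      ph <- ph + rnorm(length(ph), 0, p$sigma_phase_cycles)
    }
    tibble(
      animal_id = animal_id, species = p$species, state = state,
      structure = structure, level_db_spl = level_db_spl,
      frequency_hz = f, magnitude_nm = mag, phase_cycles = ph,
      noise_floor_nm = p$noise_floor_nm
    )
  }
  dplyr::bind_rows(
    one("RL", rl_mag, rl_ph),
    one("BM", bm_mag, bm_ph),
    one("stapes", st_mag, st_ph)
  )
}

# Hermitian inverse FFT: real waveform from a half-spectrum H over
# frequencies 0, df, ..., Nyquist (length n/2 + 1, n even).
synth_waveform <- function(H, n) {
  X <- complex(n)
  X[1L] <- Re(H[1L])
  X[2:(n / 2)] <- H[2:(n / 2)]
  X[n / 2 + 1L] <- Re(H[n / 2 + 1L])
  X[(n / 2 + 2L):n] <- Conj(rev(H[2:(n / 2)]))
  Re(fft(X, inverse = TRUE)) / n
}

#' Synthesise a click-evoked RL/BM waveform pair
#'
#' Inverse Fourier synthesis of the model's frequency responses multiplied
#' by the spectrum of a 10-us rectangular pressure pulse, sampled at 200 kHz
#' and delayed by the middle-ear delay. The RL path applies the click
#' phase-difference law `0.5 - f * delta_tau_click` and a mildly
#' low-frequency-weighted magnitude ratio (calibrated to the first-peak
#' ratio at 90 dB-p), so in the sensitive state the two first peaks have
#' opposite polarity, the RL peak arrives `delta_tau_click` later, and the
#' RL first period slightly exceeds the BM's. The BM click grows
#' proportionally with level. Polarity is normalised so the BM first peak is
#' positive (toward scala vestibuli).
#'
#' @inheritParams make_spectra
#' @param level_db_p Peak-equivalent click level in dB re 20 uPa.
#' @param delta_tau_s Optional override of the click latency difference.
#' @return Time-series tibble with RL and BM records.
#' @export
make_click_pair <- function(params, animal_id, level_db_p,
                            state = c("sensitive", "postmortem"),
                            noise = TRUE, delta_tau_s = NULL) {
  if (!inherits(params, "cochlea_params")) abort("params must be cochlea_params")
  state <- match.arg(state)
  p <- params
  tau <- delta_tau_s %||% p$delta_tau_click_s
  n <- round(p$click_dur_s * p$fs_hz)
  if (n %% 2 != 0) n <- n + 1L
  f <- (0:(n / 2)) * p$fs_hz / n
  fq <- pmax(f, p$f_step_hz)  # guard the DC bin in log-based laws

  # click BM path: causal low-order bandpass around BF (gammatone-style
  # complex poles) whose impulse response rises within the first cycle, so
  # the first displacement peak is a substantial fraction of the maximum.
  # The BM click grows proportionally with level: the shape is fixed.
  b <- p$bf_hz / p$click_q
  gtone <- function(fc, bw) (1 / (1 + 1i * (f - fc) / bw))^p$click_order
  pulse <- ifelse(f == 0, 1, sin(pi * f * p$click_pulse_s) / (pi * f * p$click_pulse_s))
  delay <- exp(-2i * pi * f * p$t_me_s)
  Hb <- gtone(p$bf_hz, b) * pulse * delay
  Hb[1L] <- 0

  if (state == "sensitive") {
    # inverted, delayed RL path with a small admixture of a slower, causal
    # bandpass centred below BF: the RL starting frequency is then lower,
    # so its first period exceeds the BM one
    fc_lo <- p$click_lf_center_frac * p$bf_hz
    w_lo <- p$click_lf_frac / (1 - p$click_lf_frac)
    Hmix <- gtone(p$bf_hz, b) + w_lo * gtone(fc_lo, fc_lo / p$click_q)
    Hr <- p$click_ratio * Hmix * pulse * delay * exp(2i * pi * (0.5 - f * tau))
    Hr[1L] <- 0
  } else {
    Hr <- Hb * p$beta_pm * exp(-2i * pi * f * p$delta_pm_s)
  }

  wb <- synth_waveform(Hb, n)
  wr <- synth_waveform(Hr, n)

  # normalise: BM first substantial extremum positive, BM peak amplitude on
  # the configured scale for this level
  amp <- p$click_bm_peak_nm_90 * 10^((level_db_p - 90) / 20)
  sc <- amp / max(abs(wb))
  idx <- local_extrema(wb)
  idx <- idx[abs(wb[idx]) >= 0.2 * max(abs(wb))]
  if (length(idx) > 0 && wb[idx[1L]] < 0) sc <- -sc
  wb <- wb * sc
  wr <- wr * sc

  if (noise) {
    sig <- p$click_noise_nm / sqrt(p$n_averages)
    wb <- wb + rnorm(n, 0, sig)
    wr <- wr + rnorm(n, 0, sig)
  }
  t <- (0:(n - 1L)) / p$fs_hz
  one <- function(structure, w) {
    tibble(
      animal_id = animal_id, species = p$species, state = state,
      structure = structure, level_db_p = level_db_p,
      time_s = t, displacement_nm = w
    )
  }
  dplyr::bind_rows(one("RL", wr), one("BM", wb))
}

#' Generate a full synthetic cohort
#'
#' Draws per-animal best-frequency jitter (log-normal, default sigma 3%) and
#' latency-difference jitter (animal-level plus record-level components),
#' then synthesises tone spectra at the requested levels and click pairs at
#' the requested click levels, optionally with matching postmortem records.
#' Fully reproducible: the same seed yields identical tables.
#'
#' @param params A [cochlea_params()].
#' @param n_animals Number of animals (>= 1).
#' @param levels_db_spl Tone levels in dB SPL (default 50, 60, 70, 80).
#' @param click_levels_db_p Click levels in dB-p (default none).
#' @param include_postmortem Also generate postmortem records (default
#'   FALSE).
#' @param seed Integer seed (required, for the determinism contract).
#' @return List with tibbles `spectra` and `clicks` (the latter empty if no
#'   click levels requested) and the per-animal draw table `animals`.
#' @export
#' @examples
#' coh <- make_cohort(cochlea_params("gerbil"), n_animals = 2,
#'                    levels_db_spl = c(50, 60), seed = 1)
#' dplyr::count(coh$spectra, structure)
make_cohort <- function(params, n_animals, levels_db_spl = c(50, 60, 70, 80),
                        click_levels_db_p = numeric(0),
                        include_postmortem = FALSE, seed) {
  if (!inherits(params, "cochlea_params")) abort("params must be cochlea_params")
  if (n_animals < 1) abort("n_animals must be at least 1")
  if (missing(seed)) abort("seed is required for reproducible cohorts")
  set.seed(seed)
  p <- params
  states <- if (include_postmortem) c("sensitive", "postmortem") else "sensitive"

  animals <- tibble(
    animal_id = sprintf("%s%02d", substr(p$species, 1, 1), seq_len(n_animals)),
    bf_hz = p$bf_hz * exp(rnorm(n_animals, 0, p$bf_jitter_sigma)),
    tau_animal_s = rnorm(n_animals, 0, p$tau_sd_animal_s),
    tau_click_s = p$delta_tau_click_s + rnorm(n_animals, 0, p$tau_click_sd_s)
  )

  spectra <- purrr::pmap_dfr(animals, function(animal_id, bf_hz, tau_animal_s, tau_click_s) {
    pa <- params
    pa$bf_hz <- bf_hz
    purrr::map_dfr(states, function(st) {
      purrr::map_dfr(levels_db_spl, function(lv) {
        tau_rec <- p$delta_tau_tone_s + tau_animal_s +
          rnorm(1, 0, p$tau_sd_record_s)
        make_spectra(pa, animal_id, lv, state = st, noise = TRUE,
                     delta_tau_s = tau_rec)
      })
    })
  })

  clicks <- if (length(click_levels_db_p) > 0) {
    purrr::pmap_dfr(animals, function(animal_id, bf_hz, tau_animal_s, tau_click_s) {
      pa <- params
      pa$bf_hz <- bf_hz
      purrr::map_dfr(states, function(st) {
        purrr::map_dfr(click_levels_db_p, function(lv) {
          make_click_pair(pa, animal_id, lv, state = st, noise = TRUE,
                          delta_tau_s = tau_click_s)
        })
      })
    })
  } else {
    tibble()
  }

  list(spectra = spectra, clicks = clicks, animals = animals)
}
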