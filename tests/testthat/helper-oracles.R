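# Closed-form OLS slope/intercept, independent of lm()
ols_oracle <- function(x, y) {
  xb <- mean(x); yb <- mean(y)
  slope <- sum((x - xb) * (y - yb)) / sum((x - xb)^2)
  c(intercept = yb - slope * xb, slope = slope)
}

# Minimal 3-point spectrum record in the TSV dialect
toy_spectrum <- function(structure, magnitude, phase,
                         f = c(10000, 26000, 30000), animal = "a1",
                         level = 30, state = "sensitive", floor = NA_real_) {
  tibble::tibble(
    animal_id = animal, species = "gerbil", state = state,
    structure = structure, level_db_spl = level,
    frequency_hz = f, magnitude_nm = magnitude, phase_cycles = phase,
    noise_floor_nm = floor
  )
}

# Decaying sinusoid click record: silent until t0, then
# A * exp(-(t - t0)/tau_env) * sin(2*pi*f*(t - t0)), sampled at 200 kHz.
toy_click <- function(f_hz, t0 = 5e-4, tau_env = 5e-4, amp = 1,
                      dur = 5e-3, fs = 2e5, structure = "BM",
                      animal = "a1", level = 90, state = "sensitive") {
  t <- seq(0, dur - 1 / fs, by = 1 / fs)
  y <- ifelse(t < t0, 0,
              amp * exp(-(t - t0) / tau_env) * sin(2 * pi * f_hz * (t - t0)))
  tibble::tibble(
    animal_id = animal, species = "gerbil", state = state,
    structure = structure, level_db_p = level, time_s = t,
    displacement_nm = y
  )
}
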