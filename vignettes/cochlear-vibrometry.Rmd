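---
title: "Timing analysis of reticular lamina and basilar membrane vibration"
author: "cochlevib"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Timing analysis of reticular lamina and basilar membrane vibration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cochlevib)
library(dplyr)
```

## The scientific problem

Outer hair cells (OHCs) are thought to amplify the sound-evoked traveling
wave on the basilar membrane (BM) through cycle-by-cycle force feedback. A
central, testable aspect of any feedback account is *timing*: does the
OHC-driven reticular lamina (RL) — the apical surface of the organ of Corti
into which the OHC tops insert — move before or after the BM? Heterodyne
low-coherence vibrometry can measure sub-nanometre displacements of both
structures in the living cochlear base, producing two kinds of records:

* **tone-evoked spectra** — displacement magnitude (nm) and phase (cycles)
  versus stimulus frequency at a series of sound levels, plus a stapes
  reference and a per-frequency noise floor;
* **click-evoked waveforms** — displacement versus time at 200 kHz sampling,
  synchronously averaged.

`cochlevib` implements the full analysis chain from these records to the
headline statistics: phase-slope latency differences, grouped statistics with
level-invariance tests, complex decomposition of the RL motion into passive
and OHC-driven components, click first-peak features, and longitudinal
(frequency-to-place) reconstructions. A calibrated synthetic generator
produces data with the same statistical structure so every stage is testable
without instrument access.

## Phase-slope latency estimation

For a pure latency $\tau$, phase lag grows linearly with frequency,
$\phi = 2\pi f \tau$. The package stores phase in **cycles** throughout
(1 cycle = 360°), so for the RL–BM phase difference
$\Delta\phi(f) = \phi_{RL}(f) - \phi_{BM}(f)$ an ordinary least-squares fit
of $\Delta\phi$ on $f$ gives the latency difference directly as the negated
slope:

$$\Delta\tau = -\frac{d\,\Delta\phi}{d f} \quad \text{(s, with } \Delta\phi
\text{ in cycles)}.$$

Positive $\Delta\tau$ means the RL phase falls faster with frequency — the
RL vibrates *after* the BM. Working in cycles avoids the $2\pi$ bookkeeping
of radian or degree conventions; converters exist at the boundary
(`cycles_to_degrees()`).

Choices that needed making:

* **Fit range.** No standard exists for the regression band; the package
  defaults to $[0.1\,\mathrm{BF}, \mathrm{BF}]$, where the best frequency
  (BF) is the BM magnitude peak. The range is always recorded in the output.
* **BF determination.** Conventionally the BF is read from the BM response
  at 30 dB SPL. Cohorts measured only at 50–80 dB SPL lack that record, so
  `latency_by_record()` uses each animal's BM spectrum at the *lowest level
  present*. At low levels the peak is level-stable, so this is a faithful
  surrogate.
* **Weighting.** Plain OLS; points at or below the per-frequency noise floor
  are excluded (`above_noise` flag) rather than down-weighted.
* **Grouping.** Each animal × level record is one observation; a 7-animal,
  4-level cohort yields $n = 28$. Mean ± SEM and a one-way fixed-effects
  ANOVA across levels (`level_invariance_anova()`) mirror the field's
  standard reporting. A mixed model with animal as a random effect is
  deliberately out of scope. Species comparisons
  (`compare_latency_groups()`) report both the pooled-variance Student t and
  the Welch variant, because published t statistics often do not identify
  which was used and the two species' variances differ appreciably.

## Active-component decomposition

Under the two-component view, the measured RL phasor is the sum of a passive
part that follows the BM and an OHC-driven part:
$D_{OHC}(f) = D_{RL}(f) - D_{BM}(f)$, computed per frequency on the complex
plane (`subtract_active()`). The subtraction is only meaningful within one
stimulus condition, so the function refuses to pair records across levels or
states. The per-frequency dominance index $|D_{OHC}|/|D_{RL}|$ is near 1
when the RL is dominated by OHC drive (low levels near BF) and near 0 when
it passively rides the BM (postmortem). Output phase is unwrapped along
frequency, anchored at the lowest frequency, as everywhere in the package.

## Click-evoked features

The click analysis extracts, per record: the first displacement peak (time,
sign, magnitude), the first period, and — for an RL/BM pair — the in-phase
time. Conventions:

* **Sign.** Positive displacement is motion toward the scala vestibuli.
* **Sub-sample interpolation.** First-peak and period times are refined by a
  parabola through the extremum and its two neighbours; at 5 µs sampling
  this is what resolves ~30 µs latency differences to ~1 µs.
* **Detection threshold.** An extremum counts as a response peak when its
  amplitude exceeds `threshold_mult` (default 3) times the baseline RMS
  *and* `peak_frac` (default 0.1) times the record's maximum absolute
  displacement, and lies after the baseline window. The relative floor is
  needed because Gaussian baseline noise exceeds any fixed RMS multiple with
  non-negligible probability over hundreds of samples; without it the
  "first peak" of a clean record can be a noise excursion. Genuinely small
  responses (e.g. BM clicks below ~70 dB-p) still fail detection, as they
  should.
* **Baseline window.** The first 5 % of the record (default). With typical
  middle-ear delays the response onset falls near 0.4 ms, so a longer window
  would overlap the response and inflate the noise estimate.
* **In-phase time $T_C$.** The moment the two structures stop moving in
  opposite directions is identified visually in experimental work; the
  package needs an operational rule and uses the first time after both
  first peaks at which the difference of the analytic-signal (Hilbert)
  phases crosses zero modulo one cycle, linearly interpolated between
  samples. This definition is this package's own.

## Frequency-to-place mapping

Longitudinal patterns are reconstructed by mapping stimulus frequency to
cochlear place with a log-linear percent-distance map
$d\% = a - b \log_{10}(f/\mathrm{kHz})$ scaled by the BM length
(`place_map()`). Map constants are configuration, not hard-coded science:
the shipped `place_map_gerbil()` preset is a basal-region approximation with
the Greenwood-style slope $b = 100/2.2$ %/decade on an 11.1 mm membrane,
calibrated so 26 kHz falls 2.05 mm from the base. It is labelled an
approximation because the published gerbil frequency-position function's
exact constants were not available for transcription; outside roughly
5–40 kHz the log-linear form should not be trusted. Snapshot waveforms are
$W(x;t) = \mathrm{mag}(x)\cos(2\pi(ft + \phi(x)))$ with the stored phase
entering with a plus sign, so a larger lag shifts the local waveform later.

## The synthetic cochlea generator

`cochlea_params()` + `make_spectra()` / `make_click_pair()` / `make_cohort()`
encode the *descriptors* of basal-turn measurements, not cochlear
biophysics. All functional forms below are plumbing choices; the calibration
constants are the quantities the analysis chain must recover.

**Tone model.** The BM magnitude is a passive log-Gaussian profile (broad
peak at `passive_peak_frac` · BF = 0.85 BF; widths 2 and 15 dB/octave² below
and above) plus an active amplitude component centred at BF:
$|D_{BM}| \propto P(f)\,(1 + A(L)\,S(f))$. The active gain $A(L)$ is
calibrated in closed form so that growth at BF from 30 to 80 dB SPL is
compressed by exactly `c_bm_db` = 23 dB, and the active Gaussian
($\sigma$ = 0.3 octaves) is centred a hair above BF so that at 30 dB SPL its
pull exactly cancels the passive profile's local slope — the low-level peak
then sits exactly at BF and drifts downward as level rises, as measured
responses do. The RL equals the BM times a ratio law that is 10 at BF at
30 dB SPL and 1.5 at 80 dB SPL (log-level interpolated) with an extra
low-frequency term growing with level, and its phase obeys
$\Delta\phi(f) = 0.5 - f\,\Delta\tau$ cycles: exactly half a cycle of
opposition at low frequency, decaying at the delay slope. These choices make
two facts *emergent* rather than imposed: RL compression comes out as
$23 + 20\log_{10}(10/1.5) \approx 39.5$ dB, and the phase-difference law at
10 Hz is 179.94°, both recovered by the pipeline.

**Click model.** The BM click is the 10 µs rectangular pulse through a
causal order-2 gammatone-style bandpass at BF (quality factor 4), delayed by
a middle-ear/speaker constant (0.365 ms) and scaled linearly with level.
A causal low-order filter is essential: its impulse response rises within
the first cycle, so the first extremum is a substantial fraction of the
maximum and first-peak detection is insensitive to the 8-fold RL/BM
amplitude difference. The tone model's dispersive traveling-wave phase
would instead smear the onset into a slow glide whose "first peak" depends
on amplitude. The RL click is the inverted, `delta_tau_click_s`-delayed,
8-fold-scaled BM shape with a small causal admixture (weight 0.15) of a
bandpass centred at 0.75 BF, which lowers the RL starting frequency so its
first period exceeds the BM's. Tone and click delays are separate
parameters (17.9 µs and 32.6 µs for the gerbil preset) because the two
stimulus types genuinely yield different values in vivo.

**Postmortem mode** zeroes the active terms: the BM becomes the passive
profile with linear (equal-dB-step) growth and a broad peak below BF, and
the RL passively follows it, $D_{RL} = \beta\,D_{BM}e^{-i2\pi f\delta}$
($\beta$ = 0.7, $\delta$ = 5 µs), which removes the half-cycle opposition
and flips the RL click polarity.

**Dispersion and noise.** Per-animal BF jitter is log-normal with σ = 3 %.
The tone latency difference carries an animal-level (1.5 µs) and a
record-level (2.6 µs) Gaussian component — total SD ≈ 3 µs, chosen so a
28-record cohort shows the ~0.6 µs SEM reported for such measurements; the
click delay carries a 4.7 µs per-animal SD matching a 1.5 µs SEM at n = 10.
Measurement noise is multiplicative log-normal on magnitude
(σ = 0.05 log₁₀-units), additive on phase (σ = 0.02 cycles, independent of
SNR — a simplification), additive Gaussian on click samples (0.2 nm single
sweep, averaged 100×), plus a reported 10⁻⁴ nm noise floor. Mouse preset:
BF 48 kHz, tone delay 12.1 µs, tighter postmortem coupling (β = 0.95).

**What the generator does not emulate:** absolute displacement calibration,
SNR-dependent phase noise, level-dependent tuning asymmetries beyond the
compression law, two-tone interactions, and any spatial coupling along the
cochlea. Passing recovery tests on these synthetics therefore demonstrates
the correctness of the estimators, not the realism of cochlear mechanics.

## Numerical choices

* Unwrapping is anchored at the lowest frequency; adjacent true steps must
  stay below half a cycle (guaranteed on the 0.2 kHz grid).
* BF ties break toward the lowest frequency, deterministically.
* The DPOAE rule is strict: a drop of exactly 5 dB is insensitive.
* A zero denominator in a transfer ratio yields a flagged undefined point,
  not an error; a zero-magnitude phasor takes phase 0 by convention.
* Quadratic refinement degenerates gracefully (vertex at the sample) when
  the three-point curvature vanishes or the extremum sits at a record edge.
* Problem sizes in the test-suite recovery loops (e.g. 3-animal, 2-level
  cohorts, 20–100 replicates) are chosen to exercise the statistics at
  second-scale runtimes; the full study-sized cohorts (7 × 4 tone records,
  10 click animals) are used for the headline recovery checks.

## Known limitations

* The latency estimate assumes $\Delta\phi(f)$ is linear over the fit band;
  real curvature (frequency-dependent delay) biases $\Delta\tau$ toward the
  band average, which is why the fit range is a logged, first-class
  parameter.
* Treating animal × level records as independent slightly understates the
  SEM when animal-level variance dominates; the package mirrors the field's
  reporting convention rather than fitting a mixed model.
* $T_C$ depends on the analytic-signal phase of short, non-stationary
  bursts and is sensitive to band overlap; it is reported with a `defined`
  flag rather than an error when no crossing exists.
* The gerbil place map is an approximation valid near the base only.
```{r example}
params <- cochlea_params("gerbil")
cohort <- make_cohort(params, n_animals = 7,
                      levels_db_spl = c(50, 60, 70, 80), seed = 1)
estimates <- latency_by_record(cohort$spectra)
group_latency(estimates)
level_invariance_anova(estimates)
```
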