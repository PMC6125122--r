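# cochlevib

Analysis of in-vivo cochlear vibrometry: the timing, magnitude and
composition of **reticular lamina (RL)** versus **basilar membrane (BM)**
vibration in the cochlear base.

Interferometric vibrometry of the living cochlea produces tone-evoked
transfer functions (displacement magnitude and phase versus frequency at
several sound levels) and click-evoked displacement waveforms for the two
structures. The scientific questions these data answer — does the
outer-hair-cell-driven RL move before or after the BM, by how much, and how
does the active component behave — reduce to a small set of estimators that
this package implements end to end, together with a calibrated synthetic
generator so that every estimator is verifiable by parameter recovery.

## What it computes

* **Transfer-function analysis** — magnitude ratios between structures,
  nonlinear compression in dB
  (`compression = ΔL − 20·log10(displacement fold)`), best-frequency
  determination, phase unwrapping in cycles, DPOAE sensitivity QC
  (sensitive ⇔ drop < 5 dB).
* **Phase-slope latency** — with phase in cycles, a pure latency τ gives
  `φ = f·τ`, so the RL−BM latency difference is the negated OLS slope of
  `Δφ(f) = φ_RL − φ_BM` over a stated frequency band (default
  `[0.1·BF, BF]`): `Δτ = −dΔφ/df`. Positive Δτ = RL later. Grouped
  mean ± SEM, one-way level-invariance ANOVA, and Student/Welch two-group
  comparisons.
* **Active decomposition** — complex vector subtraction
  `D_OHC(f) = D_RL(f) − D_BM(f)` isolating the outer-hair-cell-driven RL
  component, with a per-frequency dominance index `|D_OHC|/|D_RL|`.
* **Click features** — first-peak time (quadratic sub-sample
  interpolation), polarity (+ toward scala vestibuli), first period,
  in-phase time via analytic-signal phases, and the click latency
  difference `Δτ = T_B − T_A`.
* **Place snapshots** — log-linear frequency-to-place mapping
  (`d% = a − b·log10(f/kHz)`), longitudinal profiles, and time snapshots
  `W(x; t) = mag(x)·cos(2π(f·t + φ(x)))`.
* **Synthetic cochlea** — a two-component generator (compressive BM +
  delayed, sign-inverted active RL component; postmortem mode; gerbil and
  mouse presets) with cohort-level dispersion and noise.

Everything is tidyverse-shaped: functions take a data frame first and
return tibbles, fitted objects have `tidy()`/`glance()` methods, and
`plot_*()`/`autoplot()` functions produce ggplots.

## Worked example

Simulate a study-sized gerbil cohort (7 animals × 4 sound levels), estimate
the per-record latency difference by phase-slope regression, and summarise:

```r
library(cochlevib)

params <- cochlea_params("gerbil")
cohort <- make_cohort(params, n_animals = 7,
                      levels_db_spl = c(50, 60, 70, 80), seed = 1)

estimates <- latency_by_record(cohort$spectra)
group_latency(estimates)
#> # A tibble: 1 × 4
#>    mean   sem     n unit
#>   <dbl> <dbl> <int> <chr>
#> 1  18.2 0.548    28 us

level_invariance_anova(estimates)
#> # A tibble: 1 × 5
#>   statistic p_value df_between df_within n_groups
#>       <dbl>   <dbl>      <dbl>     <dbl>    <int>
#> 1    0.0645   0.978          3        24        4
```

The cohort mean recovers the injected 17.9 µs RL−BM latency difference
within its standard error (18.2 ± 0.55 µs, n = 28), and the ANOVA confirms
the estimate does not depend on sound level (F ≈ 0.06, p ≈ 0.98), which is
what justifies pooling records across levels.

Click-evoked responses give an independent, time-domain estimate:

```r
clicks <- make_cohort(params, n_animals = 10, levels_db_spl = numeric(0),
                      click_levels_db_p = 90, seed = 7)$clicks
lat <- click_latency_difference(click_features(clicks))
group_latency(lat)
#> # A tibble: 1 × 4
#>    mean   sem     n unit
#>   <dbl> <dbl> <int> <chr>
#> 1  34.0  1.42    10 us
mean(lat$peak_ratio)
#> [1] 8.873186
```

The RL first peak is negative (toward scala tympani) while the BM first
peak is positive, their latency difference averages ~33 µs at 90 dB-p, and
the RL peak is ~8-fold larger — the click-path calibration marks of the
generator, recovered by the feature extractors.

File-based workflows use two documented TSV dialects
(`read_spectra()`/`write_spectra()`, one row per frequency:
`animal_id species state structure level_db_spl frequency_hz magnitude_nm
phase_cycles noise_floor_nm`; `read_timeseries()`/`write_timeseries()`, one
row per sample: `animal_id species state structure level_db_p time_s
displacement_nm`; tab-separated, header required, UTF-8, `.` decimal), and
`vibrometry_report()` aggregates a dataset into one tidy table of headline
quantities.

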