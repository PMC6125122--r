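Package: cochlevib
Title: Analysis of Reticular Lamina and Basilar Membrane Vibrometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing in-vivo cochlear vibrometry measurements of
    the reticular lamina (RL) and basilar membrane (BM). Covers tone-evoked
    transfer functions (magnitude ratios, compressive growth, best-frequency
    determination, phase unwrapping, DPOAE sensitivity checks), phase-slope
    estimation of the RL-BM latency difference with grouped statistics and
    level-invariance tests, complex vector decomposition isolating the outer
    hair cell-driven RL component, click-evoked waveform features (first-peak
    latencies, polarity, first periods, in-phase time), frequency-to-place
    mapping with longitudinal snapshot reconstruction, and a calibrated
    synthetic cochlea generator for end-to-end parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
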