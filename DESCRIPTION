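Package: fnirsim
Title: Simulation of Hemodynamic Oscillation Detectability in Time-Domain and
    Continuous-Wave fNIRS
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Synthesizes time-domain functional near-infrared spectroscopy
    (fNIRS) measurements of tissue carrying periodic hemodynamic oscillations
    and analyzes their detectability. Provides analytic time-domain diffusion
    forward models for a homogeneous slab and a two-layer finite cylinder,
    sinusoidal oxy-/deoxy-hemoglobin perturbations mapped to absorption via
    Beer's law, Poisson-noise photon time-of-flight (DTOF) synthesis,
    DTOF time-gating, depth-resolved absorption retrieval via time-dependent
    mean partial pathlengths (TMPP), continuous-wave modified Beer-Lambert
    retrieval, and Fourier-domain contrast statistics with power-law scaling
    reports over acquisition parameters (photon budget, measurement length,
    sampling rate, source-detector distance).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
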