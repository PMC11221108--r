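# fnirsim

Simulation and analysis toolkit for assessing how well time-domain (TD) and
continuous-wave (CW) functional near-infrared spectroscopy (fNIRS) can detect
periodic hemodynamic oscillations — cardiac pulsation, Mayer waves and other
resting-state rhythms — in diffusive tissue, and how well TD measurements can
localize them in depth. It is aimed at researchers designing fNIRS protocols
(choosing photon budget, measurement length, sampling rate and source-detector
distance) and at developers of depth-resolved TD analysis pipelines.

## What it computes

Everything is simulated end to end:

1. **Tissue dynamics.** Oxy- and deoxy-hemoglobin concentrations (baselines
   30 and 20 uM) oscillate sinusoidally,
   `c(t) = c0 (1 + a sin(2 pi f t + phi))`, per layer and species, with
   independent random phases. Beer's law maps concentrations to the absorption
   coefficient mu_a(lambda, t) at 690 and 830 nm; reduced scattering follows
   the Mie power law `mu_s'(lambda) = a (lambda0 / lambda)^b`.
2. **Photon transport.** Analytic time-domain diffusion Green's functions with
   extrapolated boundary conditions: an image-source solution for a 5-cm
   laterally infinite homogeneous slab, and a radial-eigenfunction (Bessel
   mode) solution for a two-layer finite cylinder (radius 10 cm; 1-cm
   superficial "UP" layer over a 4-cm deep "DW" layer), assembled in the
   temporal frequency domain and inverted by FFT.
3. **Acquisition.** Each frame's distribution of photon times of flight
   (DTOF) is scaled so the baseline curve integrates to the photon budget
   `N_tot` and receives independent per-bin Poisson noise; the instrument
   response is an ideal delta (a unit-area convolution kernel is available).
   DTOFs can be sliced into ten 500-ps gates or integrated to a CW intensity.
4. **Analysis.** Signals are detrended with a 3rd-order polynomial; the PSD is
   the un-windowed one-sided periodogram; peaks are scored by the contrast
   `C(f) = PSD(f) / eps` (in dB, `10 log10`), where `eps` is the mean PSD in a
   noise-only band (above 5 Hz, or 2-2.5 Hz at low sampling rates), against a
   15-dB significance threshold.
5. **Retrieval.** Baseline optical properties are recovered by a
   Levenberg-Marquardt homogeneous-model fit; per-layer absorption changes by
   the time-dependent mean partial pathlength (TMPP) method — weighted
   least-squares inversion of `R(t) = R0(t) exp(-sum_j dmu_a,j L_j(t))` over
   gates, with `L_j(t) = -d ln R / d mu_a,j` from finite differences of the
   bilayer model; CW absorption changes by the modified Beer-Lambert law; and
   hemoglobin changes by 2x2 spectral unmixing.

## Worked example

Sweep the photon budget at a 4-cm source-detector distance and fit the
scaling laws of the 1-Hz intensity peak:

```r
library(fnirsim)

cfg <- scenario_config("H_Ntot", seed = 1, sdd = 4, wavelengths = 690)
res <- run_case(cfg)
res[, c("n_tot", "peak_psd", "epsilon", "contrast_db")]
#>   n_tot     peak_psd    epsilon contrast_db
#> 1 1e+04     48106635   1005.898    46.79651
#> 2 1e+05   4821687535  10330.270    56.69087
#> 3 1e+06 481900833673 100963.516    66.78793

scaling_report(res, "n_tot")
#>   sdd wavelength   metric n_points max_dev_pct  exponent prefactor r_squared
#> 1   4        690 contrast        3    170.8046 0.9995711 4.7641822 0.9999657
#> 2   4        690  epsilon        3    169.7163 1.0008052 0.1006740 0.9999615
#> 3   4        690 peak_psd        3    196.9987 2.0003763 0.4796291 1.0000000
```

The 1-Hz peak grows with the square of the photon budget, the noise floor
grows linearly, so the detection contrast improves linearly — at 10^6 photons
per frame the peak stands ~67 dB above the Poisson floor. Depth selectivity of
the bilayer medium:

```r
prof <- gate_contrast_profile(scenario_config("B_DW", seed = 1,
                                              n_tot = 1e6, sdd = 4))
prof[c(1, 2, 11), c("gate", "contrast_db", "significant")]
#>   gate contrast_db significant
#> 1    1    3.196587       FALSE
#> 2    2   36.749407        TRUE
#> 3   CW   54.906350        TRUE
```

With the oscillation confined to the deep layer, the first 500-ps gate — whose
photons never travel deeper than the 1-cm superficial layer — stays at the
noise level while later gates and the CW integral see the oscillation.
`run_tmpp_case()` carries this through to depth-resolved hemoglobin spectra,
and `run_cw_retrieval()` to the CW modified Beer-Lambert equivalents.

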