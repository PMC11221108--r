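---
title: "Methods: simulating and detecting hemodynamic oscillations in TD/CW fNIRS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and detecting hemodynamic oscillations in TD/CW fNIRS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models behind `fnirsim`, the numerical choices
made where several defensible options existed, and what the synthetic data do
and do not tell you about real measurements.

## The physical model

### Tissue and chromophores

The probed medium is either a homogeneous 5-cm slab or two stacked cylinders
(radius 10 cm; a 1-cm superficial layer "UP" over a 4-cm deep layer "DW"),
refractive index 1.4 throughout. Only oxy- and deoxy-hemoglobin absorb;
baselines are 30 and 20 uM. Their concentrations oscillate sinusoidally:

$$c(t) = c_0\,\bigl(1 + \textstyle\sum_k a_k \sin(2\pi f_k t + \varphi_k)\bigr),$$

with amplitude `a` a fraction of baseline (default 1%, the low end of
physiological pulsatile amplitudes) and frequency 1 Hz (cardiac) or 0.2 Hz in
the mixed-frequency scenarios. Beer's law maps concentrations to
$\mu_a(\lambda, t)$ at 690 and 830 nm using specific absorption factors
shipped as data (`inst/extdata/hemoglobin_extinction.csv`, a standard
published compilation of molar extinction coefficients pre-multiplied by
$\ln 10 \cdot 10^{-6}$ so that $\mu_a = \text{factor} \times c_{\mu M}$ with
no logarithm-base ambiguity at run time). Reduced scattering follows
$\mu_s'(\lambda) = a(\lambda_0/\lambda)^b$ with $a = 10\,\mathrm{cm^{-1}}$,
$b = 1$, $\lambda_0 = 690$ nm, so $\mu_s'(690) = 10\,\mathrm{cm^{-1}}$ and
scattering decreases with wavelength.

Phases are drawn independently per (layer, species) — the relative phase of
oscillations across compartments and species is not physiologically settled,
so the default is maximally agnostic. Each phase comes from its own
deterministic sub-stream of the master seed, keyed by layer, species and
frequency; a consequence worth knowing is that the UP-layer oscillation of a
given scenario seed is *identical* whether or not the DW layer is also
perturbed, which is what makes the no-cross-talk comparisons exact rather
than statistical. `phase_mode = "in_phase"` / `"out_of_phase"` lock the deep
layer to the superficial phase (offset 0 or $\pi$).

### Photon transport

Both geometries are solved with the time-domain diffusion approximation,
extrapolated-boundary condition (EBC) and Fick's-law detection:

- **Slab:** the classic image-source expansion. Source pairs are added until
  the next pair contributes less than $10^{-12}$ relative — about 7 pairs for
  a 5-cm slab, far below Poisson noise. Absorption enters exactly as
  $e^{-\mu_a v t}$, which the synthesizer exploits as a fast path.
- **Bilayer cylinder:** expansion in the radial eigenfunctions
  $J_0(s_n \rho)$ of the extrapolated cylinder ($s_n$ scaled zeros of
  $J_0$), with the layered one-dimensional Green's function per mode
  assembled in the temporal frequency domain and inverted to time by FFT.
  All hyperbolic ratios are rewritten in factored-exponential form (every
  exponent has non-positive real part), so the solution is overflow-safe up
  to arbitrarily large mode counts. The mode count defaults to
  $\approx (\log(1/\mathrm{tol}) + 22)\,a'/(\pi z_0) \approx 1300$ and the
  achieved zero-frequency series tail is certified against `rel_tol`
  ($10^{-8}$); an error (not a silent degradation) is raised otherwise. The
  FFT grid is zero-padded until the slowest decay mode has fallen by
  $10^{12}$ at the wrap-around time, and sampling is shifted to bin centers
  by a half-bin phase factor.

The diffusion coefficient convention is $D = 1/(3\mu_s')$ (no $\mu_a$ term)
and the EBC distance is $z_b = 2AD$ with $A$ from the Fresnel reflection
moments ($A \approx 2.95$ for $n = 1.4$ into air). Neither choice is uniquely
standard in the literature; all headline quantities are contrasts, ratios or
scaling exponents, which are insensitive to them. The two solvers are coded
independently and cross-checked: identical-layer bilayer curves match the
slab within $10^{-4}$ relative on all bins above a $10^{-6}$ dynamic-range
floor (the test asserts 1%).

### Acquisition and noise

Each frame's noiseless curve is scaled by one constant — fixed so that the
curve at *baseline* (time-averaged) optical properties integrates to the
photon budget $\bar N_{tot}$ — and every time bin receives an independent
Poisson draw. Per-bin Poisson is the physical photon-counting model; it makes
gated counts and frame totals automatically Poisson, and the shared scale
factor lets absorption oscillations modulate the detected totals (that
modulation *is* the CW signal). $\bar N_{tot}$ is therefore the expected, not
realized, baseline total. One RNG sub-stream per (wavelength, SDD) is derived
from the master seed; identical seeds reproduce every count exactly.

Bilayer synthesis would be wasteful at one solver call per frame, so the
operator precomputes curves on a node grid spanning baseline $\pm 1.5\%$ in
$\mu_a$ (5 nodes per *perturbed* layer only) and interpolates $\log R$ per
bin bilinearly; the off-grid interpolation error is below $5\times 10^{-4}$
relative (tested), two orders below the oscillation-induced changes. The
TMPP inversion never touches this grid — its pathlengths come from fresh
finite-difference solver calls — so retrieval is not circular.

The instrument response is an ideal delta. `convolve_irf()` provides
unit-area causal convolution (e.g. a Gaussian of 100-ps FWHM) as plumbing;
note that convolution conserves the curve integral only when the smeared
curve still decays inside the 5-ns window.

## The analysis chain

- **Detrending:** least-squares polynomial, order 3. At the default operating
  point (900 oscillation cycles per record) the detrender distorts the
  sinusoid by well under 1% of its amplitude; at short records the 3rd-order
  basis can absorb several percent of a slow sinusoid (at 60 cycles, about
  4%), which is why scaled-down runs should not be pushed below a few hundred
  cycles.
- **PSD:** un-windowed one-sided periodogram,
  $\mathrm{PSD}(f_k) = 2|X_k|^2/(f_s N)$ (half at Nyquist), zero-frequency
  bin excluded. This maximizes frequency resolution with no variance
  reduction. The normalization is a free convention; it is fixed,
  documented, and cancels from all contrasts and scaling exponents. Under it
  a unit-amplitude on-grid sinusoid peaks at $N/(2 f_s)$ and white noise of
  variance $\sigma^2$ floors at $2\sigma^2/f_s$ — which is what makes the
  peak scale like $T_{meas}$ and the floor like $1/f_s$.
- **Noise floor:** mean PSD over $(5, f_s/2]$ Hz when the Nyquist frequency
  exceeds 5 Hz; otherwise over $(2, 2.5]$ Hz, a band chosen to exclude a
  possible second harmonic sitting exactly at 2 Hz. (The low band is used
  for both $f_s = 5$ and $f_s = 10$ Hz, whose Nyquist frequencies are 2.5
  and 5 Hz.)
- **Contrast:** $C(f) = \mathrm{PSD}(f)/\varepsilon$, reported in dB; a peak
  is significant at $C_{dB} \ge 15$, the threshold calibrated to the maximum
  contrast Poisson noise alone produces in the noise band. The peak value is
  read at the single grid frequency nearest the target (ties toward lower
  frequency; no local-maximum search) — all shipped scenario grids place the
  perturbation frequencies exactly on-bin.
- **Power-law fits:** OLS in log-log space; $r^2$ is reported in that space,
  the space of the fit.

## Retrieval

- **Baseline fit:** Levenberg-Marquardt (via `minpack.lm`) on log-count
  residuals of the homogeneous slab model, over bins with at least 10 mean
  counts. Parameters are log-transformed (positivity); the amplitude start
  is centered analytically so the optimizer only refines curve shape.
  Defaults start at $\mu_a = 0.1$, $\mu_s' = 10\,\mathrm{cm^{-1}}$.
- **TMPP pathlengths:** $L_j(t) = -\partial \ln R(t)/\partial \mu_{a,j}$ by
  central finite differences of the bilayer solver. The step is
  $5\times10^{-4}\,\mathrm{cm^{-1}}$: large enough that log-cancellation
  noise at bins near the $10^{-6}$ dynamic floor stays an order of magnitude
  below the 0.5% total-pathlength identity
  $L_{up}(t) + L_{dw}(t) = vt$, small enough that curvature error is
  negligible ($\lesssim 10^{-4}$). `validate = TRUE` re-runs with a doubled
  step and errors if the estimates shift by more than 2% of $vt$.
- **TMPP inversion:** per frame, weighted least squares of
  $\ln(N_{g,0}/N_g) = \sum_j \Delta\mu_{a,j}\langle L_j\rangle_g$ over
  gates, with $\langle L_j\rangle_g$ the baseline-curve-weighted gate
  aggregate, weights $N_g$ (the delta-method inverse variance of
  $\ln N_g$), baseline $N_{g,0}$ the whole-measurement mean. Gates with
  mean counts below 10 are dropped (keeps the log well-behaved); zero-count
  frames enter the log with a $+0.5$ continuity correction. Passing one-bin
  gates recovers the per-time-channel form. Per-frame standard errors come
  from the weighted normal equations.
- **CW retrieval:** modified Beer-Lambert,
  $\Delta\mu_a = -\ln(I/I_0)/\langle L \rangle$, baseline $I_0$ the
  whole-measurement mean intensity and $\langle L\rangle = v\langle t\rangle$
  the photon-mean pathlength of the baseline *model* curve — self-consistent
  with the simulated physics rather than an imported literature
  differential-pathlength factor.
- **Unmixing:** per-frame $2\times 2$ solve of Beer's law at the two
  wavelengths; the condition number of the extinction matrix is attached and
  near-singular tables are rejected.

## Design choices that were genuinely open

- *Boundary condition and $D$ convention* — see above; chosen once,
  ratio-insensitive.
- *Inversion weighting.* Inverse-variance weighting is the statistically
  efficient choice and is what the package implements. It matters: with it,
  the deep-layer 1-Hz oscillation of the `B_DW` scenario remains detectable
  in the retrieved deep-layer series even at a 1-cm SDD (the late gates carry
  few but highly informative photons, and the efficient estimator preserves
  them). Pipelines that weight gates uniformly in log space are
  substantially noisier in the deep layer and can lose that peak; the
  package's acceptance suite records this divergence explicitly rather than
  tuning the weighting to reproduce it.
- *Per-bin vs per-histogram noise.* Per-bin independent Poisson implies
  Poisson totals, so nothing is lost; the converse is not true.
- *$\bar N_{tot}$ as expectation.* Treating the budget as the expected
  baseline total (not a per-frame renormalization) is what lets intensity
  fluctuate with absorption — renormalizing each frame would erase the CW
  signal entirely.
- *Degenerate inputs.* Zero-amplitude perturbations are legal and propagate
  to flat concentration series (useful as a null); `mua = 0` is legal in the
  slab (the factorization oracle); empty gates, non-positive CW frames and
  sub-threshold fits raise errors or flags rather than NaNs.

## What the generator does and does not emulate

It emulates: diffusion-regime photon migration in one- and two-layer media,
shot-noise-limited photon counting at realistic budgets ($10^4$–$10^6$
photons/frame), arbitrary sinusoidal layer/species perturbation mixes, and
the full TD gate/TMPP and CW analysis chains.

It does not emulate: instrument background or dark counts, detector
dead-time/after-pulsing, IRF jitter beyond a fixed kernel, amplitude or
frequency drift of the physiological oscillation (real peaks broaden and
bifurcate; fixed-tone results are an upper bound on detectability), more
than two layers, cerebrospinal-fluid low-scattering channels, or
radiative-transfer corrections near the source. Passing tests therefore
demonstrate correctness of the stated model and pipeline, and give best-case
detectability estimates — not guarantees for in-vivo data.

## Problem sizes

The shipped scenarios reproduce the full study grids (15-min records at
20 Hz, i.e. 18,000 frames of 625 or 250 time bins). These run in seconds to
a couple of minutes per case on one core: the slab fast path costs one
exponential per frame-bin, and the bilayer node grid costs at most
$5\times5$ solver calls per wavelength plus ten finite-difference calls for
the pathlength operator. Unit tests use shorter records (30 s–2 min, with
at least several hundred oscillation cycles wherever a spectral claim is
asserted) and the full-scale runs are concentrated in the acceptance suite.

```{r example}
library(fnirsim)
res <- run_case(scenario_config("H_Ntot", seed = 1, sdd = 4,
                                wavelengths = 690))
scaling_report(res, "n_tot")
```
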