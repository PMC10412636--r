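---
title: "Models and methods behind fluorobind"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind fluorobind}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fluorobind)
```

fluorobind implements the fitting layer of a ligand-interaction study:
titration tables, polarized intensity pairs, photon arrival streams and
infrared spectra go in; anisotropies, partition and binding constants,
FCS observables, band positions and significance flags come out. This
vignette records the models, the assumptions behind them, and the
design decisions taken where the underlying experimental conventions
leave room.

## Steady-state fluorescence

### Anisotropy

`compute_anisotropy()` evaluates `A = (I∥ − G·I⊥)/(I∥ + 2G·I⊥)`. The G
factor corrects the polarization bias of the detection path and is
treated as known (measured at the emission wavelength). For
nonnegative intensities A is confined to [−0.5, 1] and is invariant
under common scaling of both channels, so drift in lamp intensity
between readings cancels. No attempt is made to convert anisotropy
into microviscosity or an order parameter; the package reports the raw
observable and control-relative percent changes.

### Membrane partition constant

Probe-quenching titrations are analysed on the double-reciprocal line
`1/((F0/F) − 1) = (K_d/[lip])·(1/[Q]) + 1/[lip]`, with
`K_d = slope/intercept`. Two properties of this estimator matter:

* the liposome term scales slope and intercept identically, so `K_d`
  is independent of the (unit-ambiguous) liposome concentration — the
  package therefore treats `lip_conc` purely as a quenching-depth
  scale, and returns `K_d` in the unit of the quencher grid
  (micromolar in typical use);
* the reciprocal transform maps intensity noise at weak quenching into
  enormous leverage on `y = 1/((F0/F)−1)`. The fit is unweighted
  ordinary least squares, mirroring the conventional graphical
  analysis, and this caveat is the reason the noise-recovery property
  in the test suite is assessed at a realistic quenching depth
  (intensity dropping tens of percent over the titration) with
  triplicate readings averaged per concentration. With near-flat
  titrations no choice of estimator rescues the transform.

Points with `F ≥ F0` are impossible under the model but routine under
noise; they are excluded from the regression and reported by index,
never silently dropped. A non-positive fitted intercept is flagged as
a non-physical fit (error carrying the raw slope and intercept) rather
than returning a negative constant. Replicated series are fitted on
per-concentration means by default; `per_replicate = TRUE` additionally
fits each replicate so that both SD routes — replicate spread and
delta-method propagation of the fit covariance — are available. Which
of the two a published table used is usually unstated, so the package
computes both and asserts neither.

### Albumin quenching

`correct_inner_filter()` applies the standard absorbance-based
correction `F_corr = F_obs·10^((A_ex+A_em)/2)`. The analysis chain
corrects intensities before fitting whenever absorbances are supplied;
the correction is a no-op at zero absorbance.

`fit_stern_volmer()` fits `F0/F = 1 + K_SV[Q]` by OLS on molar
concentrations. The intercept is fitted freely by default and reported:
a value away from 1 is a useful diagnostic for curvature (mixed
static/dynamic quenching) or a miscalibrated control, and forcing it
to 1 is available as an option since published analyses rarely say
which was done. `K_q = K_SV/τ0` uses the conventional biopolymer
lifetime `τ0 = 5·10⁻⁹ s` as default. `fit_binding_double_log()` fits
`log10[(F0−F)/F] = log10 K_b + n·log10[Q]`; base-10 logarithms are the
convention for this plot, and at `n = 1` the model coincides with
Stern–Volmer (`K_b = K_SV`), which the test suite uses as a
cross-check between the two fitted routes.

## Single-molecule module

### The photon-stream simulator

`gen_fcs_photon_stream()` propagates point emitters by Brownian steps
(per-axis displacement `N(0, √(2·D·dt))`) through a periodic box and
draws photons from a Poisson process whose rate is the summed 3D
Gaussian detection profile
`B·Σᵢ exp(−2(xᵢ²+yᵢ²)/w0² − 2zᵢ²/(κw0)²)`. Each signal photon carries
a micro-time `offset + Exp(τ)` folded into the pulse period (the fixed
offset stands in for the instrument-response delay; the sub-100 ps
pulse width of a diode laser is negligible against nanosecond
lifetimes and is not modelled); background photons are uniform in both
times. Validity constraints are enforced at construction: box sides of
at least `10·w0` (axial side at least `10·κw0`), steps no longer than
`w0/5`, and a duration of at least 100 diffusion times.

What the simulator deliberately omits: triplet blinking,
photobleaching, detector afterpulsing and dead time, and optical
saturation — all justified by the low-excitation-power regime the
analyses assume. Passing tests therefore demonstrate correctness of
the estimator chain for an ideal dilute dye, not robustness to these
instrument artifacts. A relaxed plasmid carrying many intercalated
dyes is not explicitly modelled either; the inflated particle number
such a molecule produces is discussed below.

Default geometry: `w0 = 0.35 µm`, `κ = 5`, giving an effective volume
`V_eff = π^{3/2}·w0³·κ ≈ 1.19 fL` and hence an expected particle
number near 0.72 at 1 nM — the calibration against which folding is
judged. These values are a plausible single-photon confocal geometry
consistent with that calibration; instrument calibrations for any real
setup should replace them. The default `D = 30.625 µm²/s` puts the
simulated diffusion time at exactly 1 ms, a convenient scaled-down
reference: simulating a 70 ms species to the same statistical quality
would require correspondingly longer streams with no change in the
estimator path.

### Correlation

`correlate()` implements the standard multi-tau scheme — 8 channels
per cascade by default, first cascade twice that, counts rebinned by
summing pairs, bin width doubling per cascade — with symmetric
normalization (left/right means over the overlapping segments), which
suppresses the bias a slow drift induces in the plain normalization.
The brute-force `"direct"` scheme evaluates the exact binned
autocorrelation at arbitrary integer lags; it is quadratic-cost and
exists as the oracle against which the multi-tau bookkeeping is
validated (the two agree exactly on the first cascade, where they
process identical bins, and to within a few tenths of a percent on
rebinned cascades of a well-averaged stream). Lags are capped at a
tenth of the stream duration — beyond that the estimator variance
makes points worthless — with a warning when a longer lag is
requested.

### Fitting the correlation curve

`fit_diffusion_model()` fits the one-component 3D model
`G(τ) = (1/N)(1+τ/tD)^{−1}(1+τ/(κ²tD))^{−1/2}` by
Levenberg–Marquardt, weighted by per-lag standard errors when the
curve carries them. One component and no triplet term: samples in
this workflow are reported with a single diffusion time and measured
at low power. κ is held fixed (default 5) — with free N and tD it is
barely identifiable from a single curve and in practice comes from
instrument calibration. The particle number is the reciprocal fitted
amplitude. Starting values are derived from the curve itself
(amplitude from the earliest lags, tD from the half-amplitude lag);
non-convergence is returned as a flagged result, never silently.

### Lifetime

`fit_lifetime()` maximizes the likelihood of a mono-exponential plus
uniform background, truncated to a tail window. The window starts
0.5 ns after the peak channel of a coarse micro-time histogram by
default, which keeps the instrument response out of the fitted range
and makes deconvolution unnecessary. For a pure exponential folded
into the pulse period the truncated model is exact (the wrapped tail
is itself exponential), so the estimator is unbiased there; with
background the uniform term absorbs both true background and wrapped
photons. Standard errors come from the observed information.

### Folding interpretation

`expected_particle_number()` gives the concentration-implied PN;
`classify_folding()` calls a fitted PN "folded" within ±0.1 of it (the
conventional reporting precision of PN), "relaxed" at three times or
more, "intermediate" between. The relaxed threshold reflects that an
extended plasmid labelled along its contour behaves as several
independent emitters and overestimates PN several-fold; the factor 3
separates that regime cleanly from the folded one at these
concentrations without claiming to model the labelling statistics.

## Infrared band analysis

`find_band_peak()` works window-by-window: rubber-band (lower convex
hull) baseline correction computed over the full spectrum — a
window-local hull would chord across band tails and tilt peaks —
followed by local-maximum detection, topographic prominence filtering,
and three-point parabolic refinement of each maximum. Parabolic
refinement recovers a Gaussian band center to well under a tenth of
the sampling step (the acceptance check demands 0.05 cm⁻¹ at 0.5 cm⁻¹
sampling); its FWHM estimate is reported as a secondary diagnostic
only, since maxima positions, not band widths, are the primary
readout. Windows may return up to `max_peaks` maxima to support
phosphate-band splitting into hydration subbands; two subbands closer
than their width merge into a single maximum, in which case one peak
is returned — the package reports maxima, it does not deconvolve.
Default windows (e.g. choline 960–980 cm⁻¹, symmetric phosphate
1040–1110 cm⁻¹) bracket the standard lipid marker bands and are
plain data, overridable per analysis. `band_shift()` differences the
dominant maxima of sample and control; a missing band in either is a
classed error naming which spectrum lacked it.

## Statistics

`one_way_anova()` is the classical equal-variance decomposition (it
matches `stats::oneway.test(var.equal = TRUE)` exactly, which the test
suite asserts); degenerate inputs resolve deterministically (all
observations identical → F = 0, p = 1). `duncan_mrt()` computes
critical ranges `R_p = q(1−α_p, p, df)·√(MSE/n_h)` with the protection
level `α_p = 1−(1−α)^{p−1}`, quantiles numerically from the
studentized-range distribution — no lookup tables — and the harmonic
mean group size for mildly unbalanced designs. The stepwise procedure
never declares a range significant inside a nonsignificant enclosing
range, which makes the nonsignificance sets intervals of the sorted
means and the letter display an exact cover of them. Two-group calls
coincide with Fisher's LSD. Duncan's test is known liberal; under a
global null the control-flag rate sits above α for small designs,
which the property suite brackets at [0.03, 0.08] rather than
pretending exactness.

## Problem sizes and tolerances

The test and acceptance runs use deliberately scaled problem sizes:
titrations of 30 (membrane) or 6 (albumin) concentrations matching the
1–30 µM experimental range; one 60 s photon stream at 1 nM for the
particle-number calibration and diffusion-time recovery (tD = 1 ms);
20 s streams for the multi-seed recovery property; 10⁵ micro-times for
lifetime checks; 10⁴ null simulations for the ANOVA level; 500-seed
Monte Carlo for estimator consistency and CI coverage. Noiseless
round trips are asserted at 10⁻⁶ relative error for linear-transform
fits and 10⁻³ for nonlinear ones; stochastic recoveries at the
conventional reporting precisions (±10% tD, ±0.1 PN, ±0.1 ns LT).

## Known limitations

* All noise is either multiplicative lognormal (intensities) or
  additive Gaussian (analytic curves); correlated drift, cosmic spikes
  and detector nonlinearity are not emulated.
* The FCS chain is single-species, free 3D diffusion only — no
  anomalous diffusion, no two-component fits, no triplet correction.
* The lifetime model is mono-exponential; multi-exponential decays
  will return an amplitude-weighted compromise.
* Band analysis reports maxima, not deconvolved component bands, so
  heavily overlapped subbands are summarized by their envelope maxima.
* Replicate counts in published tables are usually unstated; where SDs
  are needed the package offers both replicate-based and
  covariance-based routes and leaves the choice to the analyst.
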