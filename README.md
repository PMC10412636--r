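# fluorobind

Quantitative analysis of how small ligands (polyphenols such as
anthocyanins, drugs, probes) interact with the three biomolecular
targets that dominate their transport and activity: **lipid membranes**,
**serum albumin** and **plasmid DNA** — from steady-state fluorescence,
single-molecule fluorescence (TCSPC-FCS) and ATR-FTIR measurements.

It is written for biophysics labs running titration-style experiments on
a fluorimeter, a confocal FCS setup or an infrared spectrometer, who
need the fitting steps between raw instrument tables and the constants a
paper reports. A synthetic-data generator with known ground truth stands
in for instrument output, so every estimator in the package is testable
end to end.

## What it computes

**Membrane probes.** Fluorescence anisotropy
`A = (I∥ − G·I⊥) / (I∥ + 2G·I⊥)` of depth-resolved probes (DPH,
TMA-DPH, MC540) reports bilayer fluidity; `percent_change()` expresses
probe intensity/anisotropy against a control. Probe-quenching
titrations yield the partition (dissociation) constant from the
double-reciprocal regression

```
1/((F0/F) − 1) = (K_d/[lip]) · 1/[Q] + 1/[lip],   K_d = slope/intercept
```

(`fit_partition()`; lower `K_d` = higher membrane affinity; the
liposome concentration cancels in the ratio).

**Albumin quenching.** After inner-filter correction
`F_corr = F_obs·10^((A_ex+A_em)/2)`, tryptophan quenching gives the
Stern–Volmer constant `F0/F = 1 + K_SV[Q]` with `K_q = K_SV/τ0`
(`fit_stern_volmer()`), and the double-log plot
`log10[(F0−F)/F] = log10 K_b + n·log10[Q]` gives the binding constant
and number of binding sites (`fit_binding_double_log()`).

**Single molecules (FCS).** `gen_fcs_photon_stream()` simulates
Brownian diffusers seen through a 3D Gaussian confocal volume,
producing TCSPC photon records (macro-time + micro-time).
`correlate()` builds the intensity autocorrelation (multi-tau or
brute-force), `fit_diffusion_model()` fits
`G(τ) = (1/N)(1+τ/tD)^−1(1+τ/(κ²tD))^−1/2` for the particle number
`PN = 1/G(0)` and diffusion time `tD = w0²/4D`, and `fit_lifetime()`
is a tail-window maximum-likelihood mono-exponential lifetime
estimator. `expected_particle_number()` and `classify_folding()` turn
a fitted PN into a DNA compaction call (a plasmid folded into a
point-like particle shows PN near the concentration-expected value).

**ATR-FTIR.** `find_band_peak()` extracts band maxima (rubber-band
baseline, prominence filtering, parabolic sub-grid refinement) in the
marker windows of `default_band_windows()` — choline, phosphate
(splitting into hydration subbands), carbonyl, methylene — and
`band_shift()` reports peak shifts against a control spectrum.

**Statistics.** `one_way_anova()` plus `duncan_mrt()` (Duncan's
multiple range test with numerically computed studentized-range
quantiles) produce letter displays and control-versus-treatment
significance flags, and `significance_table()` renders the
publication-style table.

## Worked example

```r
library(fluorobind)

## a noisy triplicate membrane titration with known ground truth
truth  <- quench_ground_truth("partition", F0 = 100, K_d = 12.97,
                              lip_conc = 2, noise_cv = 0.03, seed = 7)
series <- gen_quenching_titration(truth, 1:30, unit = "uM", replicates = 3L)
fit_partition(series)
#> Partition fit: K_d = 13.17 uM (SE 0.877), R^2 = 0.9911, 30 points used

## albumin quenching at a reported Stern-Volmer constant
sv <- gen_quenching_titration(
  quench_ground_truth("stern_volmer", F0 = 1000, K_SV = 29.37e3),
  seq(5e-6, 30e-6, by = 5e-6))
fit_stern_volmer(sv)
#> Stern-Volmer fit: K_SV = 2.937e+04 /M (SE 7.87e-12),
#>   K_q = 5.874e+12 /M/s (tau0 = 5e-09 s), intercept 1.0000, R^2 = 1.0000

## the relaxed-plasmid FCS state: 5 particles, 70 ms diffusion time
cu <- gen_correlation_curve(N = 5, tD = 0.07, kappa = 5,
                            lags = log_lags(1e-6, 10))
fit_diffusion_model(cu, kappa = 5)
#> FCS fit: PN = 5, tD = 70 ms (kappa = 5, offset 0)
```

The fitted `K_d = 13.17 ± 0.88 µM` recovers the generating 12.97 µM
within its standard error; the noiseless fits return the generating
constants to machine precision.

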