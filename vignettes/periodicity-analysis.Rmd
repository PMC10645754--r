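---
title: "Methods: periodicity analysis of dendrometer series"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: periodicity analysis of dendrometer series}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(dendrocycles)
```

This vignette documents the models, conventions and numerical choices
behind `dendrocycles`, in the order the pipeline applies them. It states
no empirical result; the numbers the package produces come from its tests
and from `scripts/acceptance.R`.

## Input preparation

Dendrometer tables arrive as delimited text with one row per observation
(timestamp, tree, species, radius in µm). Sub-hourly records are reduced
to an exact hourly grid by **instantaneous selection**: the observation
at, or nearest to, the top of each hour is taken, ties broken toward the
earlier instant, and hours with no observation within ±30 minutes are
left missing. We select rather than average because radius — and the TWD
and GRO derived from it — is a state variable: averaging a shrink–swell
cycle within an hour would bias the within-day amplitude the wavelet
stage is meant to measure. The choice is isolated in
`subsample_hourly()` should a user prefer means.

All timestamps are stored timezone-aware in UTC (input clock zones are
declared in the configuration). This matters only for the lunar stage:
synodic phase is a UTC phenomenon, and binning local-time stamps would
smear phase by up to an hour.

Vapour pressure deficit is computed from air temperature `T` (°C) and
relative humidity `RH` (%) with a Magnus-type saturation curve,

\[ e_{sat}(T) = 0.61365\, e^{17.502\,T/(240.97+T)} \;\text{kPa},\qquad
   VPD = e_{sat}(T)\,(1 - RH/100), \]

the constants of the common ecophysiological implementation; they are
arguments of `compute_vpd()` for users whose stations assume others.
`RH` outside [0, 100] is a validation error, not a clamp: such values
indicate a broken sensor file rather than physics.

The wavelet transform requires gap-free series, so meteorology is
restricted to the longest contiguous window of at least two years in
which no missing run exceeds six hours; remaining (short) gaps are filled
with the variable's long-term median over the window. Median filling
leaves the window's median invariant and is the least structured choice —
anything cleverer (diurnal interpolation, regression filling) would
inject the very periodicities under test.

## Zero-growth partitioning

The zero-growth concept assumes no irreversible growth occurs while the
stem is below its previous maximum radius. With `rmax(t)` the running
maximum over all *observed* values up to `t`:

* `TWD(t) = rmax(t) − r(t) ≥ 0` (tree water deficit, µm),
* `GRO(t) = max(0, r(t) − rmax(t−1))/Δt ≥ 0` (growth rate, µm h⁻¹),

so `TWD·GRO = 0` everywhere, radius is reconstructible as
`rmax − TWD`, and for gap-free tree series `Σ GRO·Δt` telescopes to the
net increment above the starting radius. Three conventions are fixed
here: the first observed timestep has `GRO = 0` and `TWD = 0` (there is
no previous maximum); missing radii propagate as missing TWD/GRO but the
running maximum is **carried across gaps**, because the historical
maximum is a physical state of the stem, not a property of the record;
and GRO is expressed per hour, so at hourly resolution increment and rate
coincide numerically.

Tree-level GRO values strictly exceeding 100 µm h⁻¹ are replaced by 0 —
they arise from sensor manipulation, not cambium — and the replacement
count is logged. Cleaning precedes species aggregation, which averages
all reporting trees per timestep (a single reporting tree suffices) and
imputes timesteps with no reporting tree from the species' long-term
median, again logged.

Sporadic freezing of stem water causes severe shrinkage unrelated to
transpiration. Two treatments are provided by `equalize_frozen_twd()`:
*replace* substitutes the long-term TWD median at timesteps with air
temperature below 0 °C (used, optionally, before the wavelet transform to
remove irregular multi-day freeze cycles), while *subsample* only flags
timesteps not above 0 °C for exclusion from lunar-bin averages. The
asymmetry (`< 0` vs `> 0`) follows the two operations' definitions; the
boundary value 0 °C itself is excluded only by the subsample rule.

## Wavelet transform

Series are standardized (zero mean, unit SD) so that powers are
comparable across variables and species; a constant series is an error,
as its power is undefined. The transform follows the standard
Torrence–Compo FFT formulation: zero-padding to the next power of two,
daughter wavelets `ψ̂(sω)` scaled by `sqrt(2π s/Δt)` for unit energy,
power as squared modulus, padding removed from the output. Scales map to
periods via the family's Fourier factor:
`4π/(k₀+√(2+k₀²))` (Morlet), `4π/(2m+1)` (Paul), `2π/√(m+½)` (DOG).
Morlet with `k₀ = 6` is the default — good frequency localisation at
acceptable time localisation, which suits the later attribution of
*per-period* mean power; `k₀ < 4` is rejected as inadmissible (the
zero-mean approximation of the analytic Morlet fails), Paul and DOG
orders must be positive integers.

The period grid is geometric, `p_j = p_0·2^{j/20}`, from 8 h to 1.9 years
(16,962 h) by default — 222 periods spanning sub-daily to supra-annual
oscillations. Both endpoints and the spacing are configuration keys, and
`cwt()` accepts any explicit strictly-increasing period vector, so
non-geometric reference grids can be matched exactly.

The cone of influence (largest trustworthy period per timestep, from the
wavelet's e-folding time) is computed and stored but **not** applied as a
mask: time-averaged global spectra and full matrices are reported as-is,
and masking is left to display code. Significance is assessed by
simulation rather than the analytic χ² null: pointwise p-values are the
fraction of `n_sim` standardized Gaussian white-noise surrogates whose
power exceeds the observed power at that cell (default `n_sim = 100`;
below 20 the p resolution is coarser than 0.05 and a warning is given).
By exchangeability the expected flagged fraction under the null at
α = 0.05 is `⌊0.05·n_sim⌋+1` in `n_sim+1`, i.e. ≈ 5.9% at `n_sim = 100` —
the calibration the tests check.

Numerical note: the FFT implements *circular* convolution over the padded
array. The test oracle is therefore a direct O(N²) time-domain
convolution against the periodized mother wavelet — an independent route
(time domain, no FFT) sharing the same boundary convention — and the two
agree to better than 10⁻⁶ relative power.

## Lunar ephemeris

Synodic phase is the geocentric elongation — the moon's minus the sun's
ecliptic longitude, each from truncated analytic series (20 periodic
terms for the moon, 3 for the sun) — divided by 360°, giving the fraction
of the cycle elapsed since new moon. Worst-case error is a few
arcminutes, orders of magnitude finer than the 1/12-cycle bins the
analysis uses; validity is restricted to 1900–2100, well within the
series' accuracy range. New-moon epochs are located by scanning an hourly
grid for upward zero-crossings of the signed elongation and bisecting to
under a second. The tests cross-check both phase and epochs against an
independent lunation-number polynomial oracle.

Bins are anchored at phase 0 so that bin `k` covers
`[(k−1)/12, k/12)`; only this anchoring makes the consecutive pairs 12–1,
3–4, 6–7 and 9–10 cover the new moon, first quarter, full moon and third
quarter symmetrically. The "last quartile" of moon-wood lore is
operationalized as phase ∈ [0.75, 1.0), i.e. bins 10–12. A monitoring
window is said to sample `N` lunar cycles when it contains `N` new-moon
epochs (each beginning a cycle); the count of *complete*
new-moon-to-new-moon intervals is one less and is available from the
epoch vector.

## Attribution model

For each response (GRO, TWD) the per-period mean powers are modelled as

\[ y_f = a0_{species} + s(TEMP_f) + s(VPD_f) + s(LUN_f) + \varepsilon, \]

with thin-plate regression smooths of basis dimension 10, smoothness
selected by GCV (`mgcv::gam`, `method = "GCV.Cp"`); both are
configuration keys. R² is reported **unadjusted** (`1 − RSS/TSS`), and
predictor importance as ΔR² from *refitting* without the predictor (fresh
smoothing selection), not from dropping a term's predictions — removing a
variable means removing it from the model. Two consequences are worth
stating: a nested refit can exceed the full model's R² by small
smoothing-selection noise (the tests allow 0.01), and perfectly collinear
predictors each show ΔR² ≈ 0 despite joint importance — ΔR² measures
*unique* contribution. All predictors here are smooth functions of
period, so mild compensation between temperature and VPD is expected and
real; it is the lunar term's ΔR² that carries the inferential weight.

The sensitivity sweep repeats spectra, table and models over Morlet, Paul
and DOG mothers with parameters 1–10, skipping inadmissible combinations
(logged, never coerced).

## Lunar-bin statistics

Bin means come with 95% CIs of the form `mean ± 1.96·SE`. Hourly TWD is
strongly autocorrelated, so the default SE uses an effective sample size
`n_eff = n(1−ρ)/(1+ρ)` with ρ the series' lag-1 autocorrelation (clipped
to [0, 0.999]; a naive SE is available behind the `ci` flag for exact
figure mimicry). The CIs therefore average over timesteps, not trees or
cycles — the most conservative of the defensible choices under
autocorrelation correction. The last-quartile contrast is the mean over
phase ∈ [0.75, 1) minus the mean over the rest; the moon-wood verdict is
`TRUE` only when its CI excludes 0 in the shrinkage direction (higher
TWD, lower GRO). The frost-exclusion variant drops timesteps not above
0 °C from the TWD statistics only, since freezing affects the water
signal, not the growth record.

The variability decomposition compares the **population** SD across group
means by day of year (366 groups, Feb 29 its own), hour of day (24) and
lunar bin (12). Population rather than sample SD makes the closed forms
exact (a sampled sinusoid of amplitude A has group-mean SD `A/√2`), and
the groupings are complete partitions, not samples. Each SD is also
reported as a percentage of the variable's long-term mean.

## The synthetic world

`generate_meteo()` builds temperature as annual + semiannual + daily
sinusoids plus persistent AR(1) noise, and humidity anticorrelated with
the diel temperature cycle; VPD follows through `compute_vpd()`. Default
amplitudes (annual 8–9 °C, semiannual 1.2–1.5 °C, daily 4–5 °C, AR(1)
ϕ = 0.97 with ~2 °C marginal SD) are ordinary mid-latitude values chosen
once for the two emulated site types (Baltic lowland, Alpine conifer
zone). `generate_stem_series()` composes each tree as

\[ r(t) = r_0 + G(t) − W(t) − L(t) − F(t) + \varepsilon(t), \]

with `G` non-decreasing (rate positive only while a 14-day smoothed
temperature gate is open — growth seasons emerge from climate, not fixed
dates — modulated by concurrent temperature and a nocturnal diel weight),
`W` = water gain × exponentially smoothed VPD (reversible shrinkage),
`L = A·(1 − cos 2π(phase − 0.875))/2` an injectable lunar shrinkage
peaking mid last-quartile (in the *water* term, because the moon-wood
mechanism is stem water redistribution), `F` a relaxation response to
sub-zero spells, and white observation noise. Per-tree lognormal
multipliers, Poisson sensor outages, and named seed substreams (meteo,
trees, gaps) complete the world; a given root seed reproduces every
fixture bitwise. The `paper_scale` profile is six species × five trees ×
six years (2015–2020) of hourly data; `tiny` is two species × three trees
× one year.

What the generator does **not** emulate: sap-flow or turgor mechanics,
inter-tree correlation beyond shared weather, drought legacies,
heteroscedastic sensor noise, or dendrometer drift. Passing tests on this
world therefore show that the *pipeline* recovers known structure and
does not invent lunar signal — they are not evidence about any particular
forest.

## Problem sizes and budgets in the test-suite

The suite runs the full six-year, six-species synthetic world once
(52,608 timesteps, 222-period grid) and uses a reduced world — six
species, three years, a 1-year-topped grid at 12 sub-octaves — for the
20-seed null-calibration ensemble, sizes at which the GAM has ~750 rows
per response and the lunar grid period (~709 h) is comfortably interior.
Oracle comparisons use short series (N ≤ 512), where the O(N²) direct
convolution is exact and fast. Significance calibration uses
100 surrogates, matching the default.

## Known limitations

* The ephemeris is geocentric and low-precision by design; topocentric
  corrections, moonrise/set and the anomalistic/tropical months are out
  of scope.
* ΔR² attribution inherits the identifiability limits of additive models
  under collinear predictors (documented above).
* The reader supports point-dendrometer tables only — no band
  dendrometers, no temperature-correction of sensor output, no database
  connectors.
* Wavelet coherence, cross-wavelet spectra and the inverse transform are
  not implemented; the pipeline works with marginal power only.
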