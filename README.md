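# dendrocycles

Periodicity analysis of high-frequency dendrometer records: which cycles do
tree stems actually oscillate with — and is the moon one of them?

Automatic point dendrometers record micrometre-scale changes of a tree
stem's radius every few minutes. According to the "moon wood" folk theory,
stem water content (and hence wood quality at felling) should oscillate
with the ~29.53-day synodic lunar cycle, peaking in shrinkage during the
last quartile (third quarter to new moon). `dendrocycles` provides the
full analysis chain needed to put that claim — or any other periodicity
hypothesis about stem dynamics — to a rigorous test, for ecophysiologists
and forest scientists working with hourly stem-radius and meteorology
series.

## What it computes

**Zero-growth partitioning.** A stem only grows irreversibly while its
radius exceeds its previous historical maximum; everything below that
maximum is reversible water-related shrink/swell. With `r(t)` the radius
(µm) and `rmax(t) = max_{u ≤ t} r(u)`:

    TWD(t) = rmax(t) − r(t)          (tree water deficit, µm ≥ 0)
    GRO(t) = max(0, r(t) − rmax(t−1)) / Δt   (growth rate, µm h⁻¹ ≥ 0)

so at every timestep at most one of TWD and GRO is nonzero. Tree-level GRO
spikes above 100 µm h⁻¹ (sensor faults) are zeroed; trees are averaged
into species series, with long-term-median imputation of empty timesteps.

**Continuous wavelet transform.** Standardized series (zero mean, unit SD)
are convolved with scaled Morlet (default k₀ = 6), Paul, or
derivative-of-Gaussian mother wavelets on a geometric period grid
(default 8 h to 1.9 years, 20 sub-octaves), using the standard FFT
formulation with unit-energy normalisation; power is the squared modulus
of the coefficients. Global spectra are time-averaged power per period;
pointwise Monte-Carlo significance against white-noise surrogates is
available.

**Lunar ephemeris.** Synodic phase (0 = new moon) from truncated analytic
series for the sun's and moon's ecliptic longitudes, new-moon epochs by
bisection, and the 12-interval phase binning in which bin pairs 12–1, 3–4,
6–7 and 9–10 are centred on the four principal phases.

**Attribution.** Per-period mean wavelet powers of GRO and TWD are
explained by the corresponding powers of air temperature, vapour pressure
deficit and lunar phase through a generalized additive model with
species-specific intercepts,

    GRO_f (or TWD_f) = a0_species + s(TEMP_f) + s(VPD_f) + s(LUN_f),

with thin-plate regression smooths (mgcv, GCV-selected smoothness).
Predictor importance is ΔR² = R²(model without the predictor) − R²(full
model), refit fresh for each exclusion.

**Lunar-bin statistics.** Means of TWD and GRO per phase bin with 95%
confidence intervals (AR(1)-corrected effective sample sizes), the
last-quartile contrast (phase ∈ [0.75, 1) vs. the rest) with a moon-wood
verdict, and a variability decomposition comparing the SD of group means
across days of the year, hours of the day, and the 12 lunar bins.

**Synthetic worlds.** A generator with known ground truth — seasonal
growth gated by smoothed temperature, VPD-driven reversible shrinkage,
freezing shrinkage, noise, sensor gaps, and an injectable lunar-period
component of configurable amplitude — so every stage is testable without
field data.

## Worked example

Six species, three years of synthetic hourly data with no lunar component,
full pipeline:

```r
library(dendrocycles)
cfg <- run_config(synthetic = list(profile = "paper_scale", n_years = 3),
                  min_period = 8, max_period = 8766, suboctaves = 12, seed = 1)
report <- run_pipeline(cfg)
report_headline(report)
```

```
== Attribution of per-period mean wavelet power (R2) ==
                             Growth rate Water deficit
Full model                         0.99       0.88
Excluding temperature        0.98 (-0.00) 0.61 (-0.27)
Excluding VPD                0.98 (-0.01) 0.70 (-0.18)
Excluding lunar phase        0.99 (-0.00) 0.88 (-0.00)

Overall means: GRO 0.20 um/h, TWD 21.81 um
TWD SD: day-of-year 7.04 um (32%), hour-of-day 4.40 um (20%), lunar bin 0.83 um (3.8%)
GRO SD: day-of-year 0.248, hour-of-day 0.260, lunar bin 0.021 um/h
Moon-wood last-quartile signature detected: ACPS=FALSE, CABE=FALSE, FASY=FALSE, PCAB=FALSE, PISY=FALSE, QURO=FALSE
```

Read it as: stem-dynamics spectra are almost entirely explained by
meteorology (dropping temperature or VPD costs up to 0.27 R²), while
dropping the lunar-phase spectrum costs essentially nothing (ΔR² ≈ 0.00);
lunar-bin variability is an order of magnitude below day-of-year
variability; and no species shows the last-quartile shrinkage signature.
In a world where a lunar component *is* injected
(`synth_config(..., lunar_amplitude = 15)`), the TWD spectrum develops a
peak at the ~709 h synodic period and the verdict flips — see
`tests/testthat/test-acceptance.R`.

Individual stages are exported too: `read_dendrometer_table()`,
`subsample_hourly()`, `partition_zero_growth()`, `aggregate_species()`,
`cwt()`, `significance()`, `synodic_phase()`, `phase_means()`,
`variability_decomposition()`, `delta_r2_table()`,
`mother_wavelet_sensitivity()`, and friends. See the vignette
(`vignettes/periodicity-analysis.Rmd`) for the modelling choices.

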