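# optobeat

Analysis of optogenetically modulated cardiomyocyte recordings on
multi-electrode arrays (MEAs).

Engineered cardiac monolayers expressing a photoactivatable adenylyl
cyclase (bPAC) raise their intracellular cAMP — and with it their
spontaneous beating rate — when illuminated with blue light, while a
planar MEA records extracellular field potentials from 32 sites at
25 kSa/s. optobeat implements the full readout chain for such
experiments, for electrophysiologists and bioelectronics engineers who
need reproducible, testable beating-rate and conduction analyses:

- **Preprocessing / QC** — Chebyshev type I band-pass (order 2 prototype,
  150–2500 Hz), per-channel SNR (median spike amplitude / MAD noise), and
  exclusion of channels with SNR < 2.
- **Beat analysis** — spike detection by thresholded peak identification,
  6-s segment rates from median inter-beat intervals, fold change
  *BPS/BPS₀* against the first-segment baseline, rise/decay kinetics
  (t50, t90), and per-epoch plateau summaries for light/dark cycling.
- **Activation mapping** — per-beat activation times across the array,
  thin-plate-spline isochronal surfaces *T(x, y)*, and conduction
  velocities as the inverse gradient, **v** = ∇T/‖∇T‖², summarised as the
  pooled mean speed ± SEM over all vectors on a chip.
- **Dose–response** — Hill fitting of plateau fold change versus
  irradiance *I* on the linear dose axis,
  *y = bottom + (top − bottom)·I/(I + EC₅₀)* (slope fixable at 1),
  weighted by replicates, with bootstrap confidence intervals.
- **Forward simulator** — a two-stage cascade
  *dc/dt = k_deg[c₀ + (c_max − c₀)·I/(I+K_I)] − k_deg·c*,
  *dR/dt = (R_target(c) − R)/τ_R*, an integrate-and-fire beat clock, and
  waveform synthesis with a propagating wavefront, biphasic spike
  templates, Gaussian noise and dead channels — so every stage of the
  pipeline is exercisable with no laboratory data.

The methods vignette (`vignettes/optobeat-methods.Rmd`) documents the
models, default calibration, and numerical choices in detail.

## Worked example

Simulate a 32-channel array with three dead electrodes, run the pipeline,
and fit a dose–response over the 7-level irradiance ladder:

```r
library(optobeat)

res <- run_pipeline(run_config(preset = "dead_channels", seed = 1))
res$qc
#> <qc_report> 29/32 channels included (snr >= 2)
#> # A tibble: 32 × 6
#>    channel_id rms_noise_uV peak_amplitude_uV n_spikes   snr included
#>  1          1         2.99              258.       25  86.3 TRUE
#>  ...
#>  5          5         2.96                0         0   0   FALSE

res$map
#> <activation_map> 25 beats, pooled speed 50 +/- 0.0011 mm/s (SEM, n = 34525)

ex <- run_dose_response_experiment(seed = 1, n_boot = 200)
tidy(ex$fit)
#> # A tibble: 4 × 4
#>   term   estimate conf.low conf.high
#> 1 bottom    1.000    0.999     1.00
#> 2 top       1.14     1.13      1.14
#> 3 ec50      0.551    0.528     0.577
#> 4 hill_n    1        1         1
```

Reading the output: three noise-only channels fall below the SNR ≥ 2 gate
and are excluded, leaving 29 functional interfaces. The activation map
recovers the simulated planar wavefront speed of 50 mm s⁻¹ with
near-zero SEM. The dose–response experiment (one simulated 30-min
irradiation per level, jittered beat clock) returns an EC50 of
0.551 µW mm⁻² — the simulator's half-saturating irradiance is 0.56 — with
a ~14% maximal rate elevation (`top` ≈ 1.14).

Plotting: `autoplot()` methods exist for fold-change series, activation
maps (filled-contour isochrones with electrode markers) and
dose–response fits; `tidy()`/`glance()` return broom-style tibbles for
fits and maps.

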