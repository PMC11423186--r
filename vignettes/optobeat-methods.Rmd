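---
title: "Models and methods behind optobeat"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind optobeat}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(optobeat)
```

optobeat analyses multi-electrode array (MEA) recordings of spontaneously
beating cardiomyocyte monolayers whose intracellular cAMP — and hence
beating rate — is driven by blue light through a photoactivatable adenylyl
cyclase (bPAC). This vignette explains the models the package implements,
the tunable parameters that matter, what the synthetic-data generator does
and does not emulate, and the numerical choices made where the design was
genuinely open.

## The measurement chain

A 32-element MEA (200 µm pitch, interrogating a 1000 µm × 1000 µm patch of
monolayer) records extracellular field potentials at 25 kSa/s. The analysis
chain is:

1. **Band-pass filtering** (`bandpass_filter()`): Chebyshev type I,
   prototype order 2 (4th-order band-pass), 150–2500 Hz.
2. **Channel QC** (`channel_metrics()`, `apply_qc()`): per-channel SNR;
   channels with SNR < 2 are excluded.
3. **Spike detection and beating rate** (`detect_spikes()`,
   `segment_rates()`, `fold_series()`): peak identification, 6-s segments,
   median-interval rates, fold change against the first segment (BPS₀).
4. **Kinetics** (`extract_kinetics()`, `cycle_summary()`): t50/t90 of the
   chronotropic response to light edges; per-epoch plateaus.
5. **Activation mapping** (`activation_map()`): per-beat activation times,
   thin-plate interpolation, inverse-gradient conduction velocities.
6. **Dose–response** (`fit_dose_response()`,
   `run_dose_response_experiment()`): Hill fit of plateau fold change
   versus irradiance, yielding the EC50.

## The photoresponse cascade

The simulator's core is a two-stage linear cascade driven by irradiance
$I$ (µW mm⁻²):

$$\frac{dc}{dt} = k_{deg}\left[c_0 + (c_{max}-c_0)\frac{I}{I+K_I}\right] - k_{deg}\,c,$$

$$\frac{dR}{dt} = \frac{R_{target}(c) - R}{\tau_R},\qquad
R_{target}(c) = R_0\left[1 + \delta_{max}\frac{c-c_0}{c_{max}-c_0}\right].$$

Light shifts the cAMP production/degradation balance toward a saturating
target (Michaelis–Menten in $I$, exponent 1 — a single photoreceptor
binding step); the beating rate relaxes toward a level proportional to
cAMP. This is the simplest model that reproduces the observed
phenomenology: a fast cAMP rise, a slower rate rise, a saturating
dose–response with the printed EC50, and reversible on/off cycling. At
constant irradiance the closed form

$$\frac{R_\infty}{R_0} = 1 + \delta_{max}\frac{I}{I+K_I}$$

is exposed as `steady_state_fold()` so simulations can always be checked
against the analytic limit.

### Default calibration

| parameter | default | units | rationale |
|---|---|---|---|
| `K_I` | 0.56 | µW mm⁻² | measured EC50 of the beating-rate dose–response |
| `delta_max` | 0.14 | — | 14% plateau elevation at saturating light |
| `c0`, `c_max` | 5.36, 11.04 | ng (mg protein)⁻¹ | dark vs lit intracellular cAMP |
| `k_deg` | 0.6 | min⁻¹ | cAMP rise t50 = ln2/k ≈ 1.2 min (< 2.5 min observed) |
| `tau_R` | 7 | min | beat-rate t50 ≈ 6.7 min, time-to-95% ≈ 23 min |
| `R0` | 4.3 (5.7 NT) | beats s⁻¹ | basal rates of transduced / non-transduced cultures |

Two published observations cannot be reconciled exactly by any linear
cascade: the rise t50 (6–7 min) and decay t50 (6 min) differ slightly,
while a linear system is rise/decay symmetric. The defaults put both at
≈ 6.7 min, inside both reported ranges. Similarly, plateau elevations of
14% and 17% are reported in different experiments; `delta_max` defaults to
0.14 and is configurable.

Because the cascade is linear with piecewise-constant drive,
`simulate_photoresponse()` uses an exact per-step exponential integrator
(the closed-form solution over each constant-irradiance span evaluated on
the output grid), so trajectories carry no discretization error; the test
suite cross-checks it against a general-purpose stiff ODE solver.

## Beat generation and waveform synthesis

Beats come from an **integrate-and-fire clock**: a beat fires each time
$\int R\,dt$ advances by 1. Unlike a renewal process, this preserves exact
rate tracking, which matters for kinetics recovery tests. Per-beat
Gaussian jitter (default σ = 1 ms; inter-beat variability is not
quantified in the source data, so this is a modelling choice) adds
realistic timing noise.

Each live channel receives a spike template at every beat, delayed by the
wavefront geometry — planar ($\mathbf{p}\cdot\hat u/v$) or radial
($\|\mathbf{p}-\mathbf{o}\|/v$) — on white Gaussian noise (default RMS
7 µV, within the < 10 µV operating envelope; default amplitude 300 µV,
within the > 64 µV envelope). Dead channels carry noise only.

The template blends a Gaussian lobe with a biphasic component (two
unequal-width Gaussians of opposite sign and cancelling area) through the
`morphology` parameter: −1 negative monophasic, 0 biphasic, +1 positive
monophasic, matching the morphology drift seen across culture days. The
biphasic shape deliberately has a dominant leading lobe — as extracellular
cardiac field potentials do — because a template with exactly equal lobes
makes the "largest deflection" fiducial ambiguous under sampling. The
template's reference sample sits on the dominant extremum, so detected
spike times coincide with injected beat times.

### What the generator does not emulate

No biophysical membrane model stands behind the waveforms (no
Hodgkin–Huxley dynamics, no re-entry or spiral waves), electrode coupling
is uniform, noise is white and Gaussian (no line hum, no motion
artifacts), and wavefronts are rigid with a single activation origin.
Passing tests therefore demonstrate that the *analysis chain* recovers
known ground truth under realistic amplitudes, rates and noise — not that
it is robust to every pathology of real recordings (electrode drift,
multiple activation centers, arrhythmic dynamics).

## Filtering and QC choices

The band-pass ripple is not specified by convention; 1 dB is the default
and is explicit in `filter_spec()` because a Chebyshev-I design is
underdetermined without it. "Second order" is read as the prototype
order (the band-pass transform doubles it); both readings are available
via `order`. Filtering is zero-phase (forward–backward) by default so
activation times carry no group-delay bias; `causal = TRUE` reproduces a
literal single pass. For recordings synthesized at reduced sample rates
(long-duration runs are generated at 1 kSa/s; see below) the upper band
edge is clamped to 0.45·fs by `adapt_filter_spec()`, and the spike
template is widened (12 ms) so spikes remain resolvable.

The noise scale is the MAD × 1.4826 rather than the raw standard
deviation, so spikes do not inflate the noise estimate. SNR is the median
absolute spike amplitude over that scale. A channel needs at least 3
detected spikes for its SNR to count (`min_spikes`): the rate estimator
needs 3 spikes anyway, and without the floor a single rare noise
excursion above threshold (expected ≈ 0.05 events per noise-only channel
per 6-s window) would occasionally promote a dead channel past the
SNR ≥ 2 gate.

## Beating rate, fold change and kinetics

The per-segment rate is the reciprocal **median inter-beat interval**
(≥ 3 spikes; single interval with 2; zero otherwise). A count-per-segment
estimator would quantize to 1/6 Hz and could not express plateaus like
4.67 BPS; the median is also robust to one missed beat. The array-level
rate is the median across channels with activity; both per-channel and
array-level series are returned because either aggregation is defensible.

`extract_kinetics()` smooths the fold series with a centered 5-segment
moving average (plateau values are reported at whole-minute t50
resolution in the source experiments, implying smoothing, but no method
is given), normalizes between a pre-edge baseline and the mean of the
final 20% of the epoch, and linearly interpolates the 0.5/0.9 crossings.
The baseline window defaults to the 120 s immediately before the edge: a
longer window biases the baseline when the pre-edge state is itself still
converging (e.g. light switched off after 20 min, ~96% of plateau), which
we verified inflates the decay t50 by ≈ 0.25 min against the analytic
value. When the plateau–baseline separation is under twice the series
noise scale the series is flagged unresponsive rather than reporting a
meaningless t50.

## Activation mapping

Spikes are clustered into array-wide beats around the best-covered
channel's spike train with a ±40% of median-IBI window; beats missing more
than half the channels are dropped. Two fiducials are available: the
detection extremum (default) and cross-correlation lags against the
earliest channel; they agree within 1 ms on clean data and a quality
warning is attached when they diverge.

Interpolation is a thin-plate spline (kernel $r^2\log r$ plus affine
term, zero smoothing, solved in unit-scaled coordinates for
conditioning). Thin-plate splines reproduce affine surfaces exactly, so a
planar wavefront yields an exactly planar surface and the speed estimate
is exact up to sampling quantization — this is why planar-wave tests can
assert tight tolerances. The velocity field is the inverse-gradient
$\mathbf v = \nabla T/\|\nabla T\|^2$ on a 25 µm grid (pitch/8, balancing
gradient accuracy against cost) by central differences; vectors outside
the electrode convex hull, with near-flat gradient, or faster than
200 mm s⁻¹ (near-flat-gradient blowups) are excluded. Velocity points in
the direction of later activation, i.e. of wave travel. The chip-level
summary pools vectors across all beats in the window (mean ± SEM); pooling
before versus after per-beat averaging is not distinguishable from the
published convention, and pooling all vectors is the default.

## Dose–response fitting

`fit_dose_response()` fits
$y = \mathrm{bottom} + (\mathrm{top}-\mathrm{bottom})\,I^h/(I^h + EC_{50}^h)$
by weighted least squares (weights = replicate counts) on the **linear**
dose axis, so the zero-irradiance point enters directly instead of
through a log-dose pseudo-value. The Hill slope is fixed at 1 by default
(Michaelis–Menten limit); both the slope and the bottom asymptote can be
freed. EC50 and the slope are parameterized on the log scale, which
enforces positivity without box constraints (the Levenberg–Marquardt
implementation is unreliable near bounds). Confidence intervals come from
a seeded parametric bootstrap (200 resamples) because replicate counts
are small (3–4). At σ = 0.02 response noise the Fisher information of the
7-level design caps per-fit EC50 precision near 20–30% relative error for
extreme EC50s; the fit is unbiased and attains that limit, and the test
suite asserts exactly that rather than a tighter, unattainable bound.

## Problem sizes and numerical conventions

Times are seconds from recording start; positions are µm (origin at the
lower-left electrode); voltages are µV, assumed gain-corrected.
Recordings are stored as CSV (float32 precision, lossless on round-trip)
with a JSON metadata sidecar. The default 32-electrode layout is a 6 × 6
grid at 200 µm pitch with the four corners absent — the unique plain-grid
arrangement of 32 electrodes spanning 1000 µm × 1000 µm.

Short fixtures (baseline, dead-channel) are synthesized at the full
25 kSa/s. Multi-minute photoresponse runs are synthesized at 1 kSa/s —
at 4–6 beats s⁻¹ with ≥ 100 ms inter-beat intervals, 1 kSa/s resolves
beat timing to 0.1% of an interval, and full-rate synthesis of hour-long
32-channel recordings would cost tens of gigabytes for no analytical
gain. Multi-hour presets (`bpac_cycles`, `multiday`) default to
rate-level output (`waveform = FALSE`).

All randomness flows through explicit integer seeds (default 0), with
per-stage seeds derived from one root seed; a fixed seed reproduces every
output byte-identically.

## Known limitations

- The cascade is linear, hence rise/decay symmetric; systems with
  asymmetric on/off kinetics (e.g. saturating phosphodiesterase activity)
  are outside the model family.
- `beat_cluster()` assumes a dominant, array-wide rhythm; it will not
  resolve multiple concurrent activation centers.
- The SNR definition (median spike amplitude over MAD noise) is one of
  several reasonable conventions; absolute SNR values are comparable
  within the package, not across instruments.
- EC50 precision is design-limited at high response noise (see above);
  reported bootstrap intervals convey this honestly.

## A worked end-to-end run

```{r example, eval = FALSE}
res <- run_pipeline(run_config(preset = "dead_channels", seed = 1))
res$qc          # 29/32 channels retained
res$fold        # segment-wise BPS and fold change
glance(res$map) # pooled conduction speed +/- SEM

ex <- run_dose_response_experiment(seed = 1)
tidy(ex$fit)    # bottom/top/EC50 with bootstrap CIs
autoplot(ex$fit)
```
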