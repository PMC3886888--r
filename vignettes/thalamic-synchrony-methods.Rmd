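---
title: "Thalamic population synchrony and cortical orientation information: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Thalamic population synchrony and cortical orientation information: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`thalsync` simulates how the stimulus-driven synchronization of a thalamic
(LGN) population can, by itself, produce orientation-tuned firing in a
layer 4 cortical neuron, and quantifies how the degree of synchrony shapes
the orientation information an ideal observer can decode from that neuron.
This vignette is the package's account of its models, parameters, numerical
choices, and limitations. Nothing stated here as an empirical result goes
beyond what the test suite and `scripts/acceptance.R` themselves compute.

## The scientific picture

Individual LGN relay cells respond to a drifting sinusoidal grating at
essentially the same mean rate regardless of the grating's direction. A
cortical layer 4 neuron, however, receives convergent input from roughly 30
LGN cells whose receptive fields (RFs) form a spatially compact, elongated
cluster. When the grating's drift axis is perpendicular to the cluster's
major axis, all RF centres sit at nearly the same grating phase and the
population fires in near-synchronous volleys; when the drift axis runs along
the major axis, response latencies spread across the grating period and the
population is asynchronous. A leaky cortical neuron with a short membrane
time constant is a coincidence detector, so population synchrony — not any
single neuron's rate — carries the orientation signal.

The pipeline has five stages, each a package module:

1. **Synthetic LGN templates** (`make_template_population()`,
   `simulate_lgn_responses()`): stand-ins for a small set of simultaneously
   recorded ON-centre X-cells.
2. **Population filling** (`fill_population()`,
   `assemble_population_spikes()`): expansion of the templates to a
   30-member convergent population under an RF-separation distribution,
   with each spatial shift converted to a response-latency shift.
3. **Synchrony metrics** (`pooled_autocorrelation()`, `estimate_jitter()`,
   `jitter_tuning_curve()`): population timing jitter from the pooled
   spike-time autocorrelation.
4. **Controlled synchrony + cortical model** (`jitter_profile()`,
   `controlled_population_input()`, `run_condition()`): orientation-
   dependent Gaussian timing noise sigma(theta) driving a forward-Euler
   leaky integrate-and-fire (LIF) neuron through summed exponential EPSCs.
5. **Decoding** (`fit_tuning()`, `fisher_information()`,
   `efficiency_analysis()`, `width_sweep()`): tuning curves, Poisson
   response models, Fisher information, the Cramér-Rao bound, and
   information per spike (IPS).

## Stimulus and geometry conventions

The stimulus is a drifting sinusoidal grating at 0.5 cycles/degree and 5 Hz
(period 200 ms), 100% contrast, probed at eight directions 0–315° in 45°
steps (and on finer grids for cortical tuning). Direction 0° is a vertical
grating drifting rightward; 90° a horizontal grating drifting downward.

A spatial offset `d` between two RF centres, at angle `phi` to the drift
direction, delays peak excitation by the **shift latency**

    latency = d * cos(phi) * f_s / f_t ,

i.e. 0.1 s per degree of along-drift offset at these frequencies. Latencies
are signed and deliberately not wrapped; spikes shifted past the trial
boundary are folded back by whole stimulus periods, which preserves both
counts and phase for a steady-state periodic stimulus (truncation is
available as a config switch).

## The synthetic LGN generator and its calibration

No recorded data ship with the package; the generator replaces the original
cat recordings with synthetic templates carrying the statistical structure
the downstream analysis relies on:

* **Event-based cycle response.** Each grating cycle evokes one response
  event per neuron at a phase fixed by the RF centre's projection on the
  drift axis. Spikes per event are Poisson; each spike is Gaussian-jittered
  around the event (`event_timescale`, default 13 ms SD) or falls in an
  exponentially decaying tail (`tail_fraction` 0.3, `tail_tau` 40 ms) —
  the sharp-onset/decaying-tail asymmetry of real grating PSTHs. An
  event-based process rather than a rate-modulated Poisson process is used
  because the jitter analysis needs identifiable events whose timing SD can
  be controlled without confounding count noise with timing noise.
* **Direction-insensitive rates.** Mean rate is 22 Hz (band 16–28 Hz);
  direction changes only the event phase, never the rate.
* **Per-trial session gain.** A multiplicative gamma-distributed gain
  (mean 1, CV 0.6), shared across the simultaneously recorded neurons
  within a trial, emulates the slow excitability fluctuations of
  anesthetized recordings. It makes single-neuron trial counts strongly
  supra-Poisson (Fano ≈ 9 for a 22-spike trial) and is the source of the
  trial-to-trial input count variability that the cortical response
  distributions inherit. A pure Poisson generator was tried first and
  produces nearly deterministic cortical counts (mean–variance slope ≈ 0),
  which contradicts the variance structure the decoding analysis is about.
* **Geometry.** Five ON-centre templates with 1.0° centre diameters, spread
  over a 1.6° × 0.45° centre region (visual-space coverage ≈ 2.6° × 1.5°,
  major axis horizontal). ON-only, identical-polarity populations are a
  deliberate simplification; OFF subfields and push–pull arrangements are
  out of scope.

`event_timescale`, the tail parameters, the cluster spans, and the RF
diameter are **calibration constants**: they were fixed once so that the
multi-trial population timing-jitter curve of the default filled population
reproduces its physiological shape — an asynchronous ceiling near 100 ms, a
preferred-orientation floor near 24 ms, and a Gaussian dip of width ≈ 31°
— and are not revisited. Two tensions are worth recording. First, the
quoted experimental coverage of such clusters (≈ 5° × 2°) is incompatible
with a ≈ 31° dip width at `f_s/f_t = 0.1 s/deg`: a 2.9° centre span makes
the 45°-off directions fully asynchronous and collapses the fitted dip to
≈ 20°, so the calibration favoured the graded jitter-curve quantities over
the prose coverage figure. Second, the hard separation-distribution support
cannot hold pairwise in a 30-member cluster (below).

Trial duration is 1 s (5 cycles) and the template set holds 30 trials per
direction; neither is experimentally constrained, and both are desk-scale
choices (enough cycles for stable counts, enough trials for a meaningful
trial-resampling distribution).

## Population filling and the separation distribution

Pairwise RF separations of LGN cells converging on one cortical target,
measured as centre distance over the larger centre diameter (RFCD), follow
a unimodal distribution supported on [0.4, 2.0]. The exact analytic form is
not recoverable from the available text, so the default `separation_model()`
is a truncated Gaussian (mode 1.0, SD 0.4) normalised on the support, and a
tabulated density can be supplied instead.

`fill_population()` places each new member at a distance drawn from the
separation model (scaled by the larger diameter) from a randomly chosen
existing member, in a uniform random direction, rejecting proposals outside
the bounding region of the template cluster ("the visual space covered does
not change") or closer than a minimum distance to any existing member.

A geometric impossibility forces one deliberate deviation: all 435 pairs of
a 30-member population cannot simultaneously satisfy separation ≥ 0.4 RFCD
and ≤ 2.0 RFCD. Points pairwise ≤ 2.0 apart fit in a disk of diameter 2.0,
and the standard circle-packing bound caps the number of points pairwise
≥ 0.4 apart in such a disk at ≈ 23–32 even for a perfect circular packing —
fewer for an elongated cluster. The upper bound *is* enforced for all pairs
(the default region diagonal is below 2.0 RFCD); the lower bound is
enforced as a soft minimum pairwise distance `0.4 * (1 - overlap_tol)` with
`overlap_tol = 0.8`. Consequently the all-pairs separation histogram is the
model *truncated by the region geometry*, not the model itself; the
anchored draws follow the model exactly, which is what the
goodness-of-fit test verifies in a large-region configuration.

Each member is a translated copy of a template and, in multi-trial
assembly, replays a randomly assigned recorded trial of that template
shifted by its own latency — the trial-to-trial variability of one neuron
standing in for across-neuron variability on a single trial.

## Timing jitter from the pooled autocorrelation

All member spike times are pooled into one train (every synapse has equal
strength, so the cortical target sees only the pooled train) and the
histogram of all pairwise time differences on lags ±400 ms, normalised to
[0, 1], is the population autocorrelation. Numerical choices:

* 1 ms bins; self-pairs excluded (they add a zero-lag delta that biases
  narrow fits); counts at ±lag are mirror images by construction.
* When the trial duration is supplied, counts are corrected for the
  finite-trial triangular envelope (lag tau is observable over
  `duration − |tau|` only), so a temporally uniform train yields a flat
  corrected autocorrelation rather than a spuriously peaked one.
* A three-parameter Gaussian (amplitude, SD, baseline ≥ 0) is least-squares
  fitted on lags within ±100 ms (excluding grating periodicity), with
  multi-start SDs of 5, 20, 80 ms. When the stimulus period is supplied the
  model adds the first periodic replicas of the central Gaussian at ±period:
  invisible for narrow fits, they absorb the mass leaking into the window
  from neighbouring response events when the jitter approaches half the
  window, which otherwise biases wide fits upward (the recovery oracle at
  40 ms injected SD exposed this).

The **response timescale** `delta_r` is the lag at which the fitted curve,
normalised to its own peak, equals `exp(-1)`; the **PSTH timing jitter** is
`delta_t = delta_r / 2`. For a Gaussian population PSTH of SD sigma the
pairwise-difference distribution has SD `sigma * sqrt(2)`, whose `exp(-1)`
lag is `2 * sigma`, so `delta_t` recovers sigma — the exp(−1) reference is
the unique level consistent with that halving relation, and a Monte-Carlo
oracle (injected SDs 5–40 ms recovered within 10%) pins it down. When the
fitted baseline is high enough that the normalised curve never reaches
`exp(-1)` within twice the window, the estimate is censored at the
window-limited ceiling `delta_t = 100 ms` — the operational meaning of
"approximately 100 ms" for an asynchronous population.

The jitter tuning curve repeats this at every direction over many (by
default 100) independent population refills (fresh placements, fresh trial assignments); its dip is
fitted with a Gaussian on the 180°-periodic distance to the preferred
direction.

## Controlled synchrony: sigma(theta)

To manipulate synchrony directly, across-neuron timing variability is
replaced by zero-mean Gaussian noise of orientation-dependent SD

    sigma(theta) = sigma_max − (sigma_max − sigma_min) *
                   exp(−d180(theta, theta_pref)^2 / (2 * width_deg^2)),

with `d180` the 180°-periodic angular distance. `sigma_min`, the value at
the preferred orientation, is the swept "minimum timing jitter"
(6–40 ms). `sigma_max = 100 ms` and `width_deg = 25°` are calibration
constants fitted by least squares (grid search, `calibrate_jitter_profile()`)
so that the controlled pipeline reproduces the multi-trial jitter curve
over the eight measured directions.

Two input constructions are exposed. `apply_controlled_jitter()` replays a
single donor trial for every member (exact control, no count variability)
and backs the calibration and monotonicity oracles. The cortical
simulations use `controlled_population_input()`: every member draws a fresh
random 0°-direction trial of its own template on every simulation trial —
phase-aligned to remove the template's 0° position phase, so the intrinsic
(baseline) across-neuron timing survives while stimulus-driven timing comes
from the geometry and sigma(theta) — then gets its position latency for the
probe direction and per-spike noise. The per-trial resampling is what gives
cortical spike counts their trial-to-trial variability.

## The cortical integrate-and-fire model

Every input spike lays down an exponentially decaying EPSC
`I0 * exp(−(t−t_k)/tau_epsc)` (equal synaptic strength; inclusive onset at
the spike's own sample), currents sum linearly, and the membrane follows

    tau_m * dV/dt = −(V − E_rest) + R_m * I_syn(t),

integrated by forward Euler at dt = 0.05 ms. Crossing threshold records a
spike, sets V to 0 mV for exactly one sample (the cosmetic spike of the
hard-reset model), then clamps V at the reset potential for the 3 ms
refractory period. Fixed constants: E_rest = −70 mV, V_reset = −65 mV,
tau_m = 2 ms, dt = 0.05 ms, t_refract = 3 ms.

`V_thresh` and `R_m` are not experimentally pinned down; the model is
robust to threshold/reset choices and sensitive to EPSC efficacy. The
defaults — V_thresh = −55 mV, R_m = 52 MΩ, I0 = 0.055 nA, tau_epsc = 4 ms
(both EPSC constants inside their effective ranges of 0.05–0.1 nA and
2–5 ms) — were set by a one-time "sufficient firing" calibration: a volley
of roughly half a dozen near-coincident EPSCs reaches threshold, the
orthogonal-direction response stays near zero, and the low-jitter tuning
HWHH lands in the mid-teens of degrees. At R_m = 100 MΩ (the obvious round
number) the cell fires ≈ 27 counts/trial even for asynchronous input and
tuning widens past 20°. Setting I0 to 0.02 or 0.2 nA reproduces the
impoverished and strong firing regimes; `classify_firing_regime()`
thresholds the preferred-orientation mean count at 2 and 60 counts/trial.

Forward Euler at dt = 0.05 ms tracks the subthreshold closed form to within
0.1% relative error on V, and halving dt changes condition mean counts by
under 2% — both asserted in the tests.

## Decoding: tuning, Fisher information, efficiency

Per direction (5° grid over a 180° span in the working profile; 1° in the
full profile) and per `sigma_min` level, trial spike counts give a tuning
curve. A local Gaussian (amplitude, centre, SD, baseline ≥ 0) is fitted on
the 180° span centred on the empirical argmax — drifting gratings are
direction-signed, so the two lobes 180° apart are analysed separately —
and HWHH = SD × sqrt(2 ln 2). Flat curves (amplitude ≤ 2% of the peak) are
flagged and excluded from information analysis.

Counts are modelled as Poisson with rate `lambda_hat(theta)`, the Gaussian
fit evaluated on a 1° grid and floored at 10⁻³ counts/trial (the closed
form divides by it). Smoothing is required because raw-rate fluctuations
are magnified by differentiation. Fisher information is computed two ways
and both are exposed: the expectation form
`E[(d log p(n|theta)/d theta)^2]` with central differences on the 1° grid
(one-sided at the edges) and zero-probability terms contributing zero (the
standard measure-zero convention, consistent with the closed form), and the
Poisson closed form `lambda'(theta)^2 / lambda(theta)`. They agree within
1% on smooth analytic tuning functions; the expectation form is the
headline number. From the peak information `J_peak`:
estimator SD `= 1/sqrt(J_peak)` (Cramér-Rao, unbiased-estimator reading),
and information per spike `IPS = J_peak / peak mean count` — the
efficiency metric. The IPS-versus-`sigma_min` curve is summarised by a
quadratic least-squares fit; its vertex is reported only when interior to
the sweep, otherwise the optimum is flagged as a boundary. The Poisson
adequacy of per-direction counts is checked by a chi-squared dispersion
test and reported rather than assumed; with the session-gain generator the
counts are in fact strongly over-dispersed (most directions reject the
Poisson null), so the Poisson response model should be read as the
decoding model of an ideal observer who tracks only the mean rate —
relative comparisons across synchrony levels, which share the same
over-dispersion, are the meaningful output.

The tuning-width sweep scales `width_deg` by factors 0.25 / 1 / 2, realising
HWHH from ≈ 4° to ≈ 25°, and reports each width's normalised IPS curve and
optimal jitter; narrow widths are simulated on a finer (2.5°) direction
grid so the thin tuning peak is resolved.

## Problem sizes

The working ("desk") profile used by the analysis scripts, the acceptance
script, and the heavier tests: 5 templates × 30 trials per direction;
30-member fills; 100 refills for jitter curves (the dip-width fit is the
most refill-hungry quantity and benefits from the extra averaging); 8 `sigma_min` levels (6–40 ms) × 36 directions (5° grid)
× 100 trials for the cortical sweep; 3 width scales × 6 levels × 72 directions × 40
trials for the width sweep. The full-resolution profile (`paper_config()`:
1° grid, 250 trials) is provided but long-running. Doubling trials beyond
the working scale changes `J_peak` estimates by a few percent at most,
consistent with the trial-sufficiency property tested at reduced scale.

## Known limitations and honest disagreements

* **What the generator does not emulate:** real spike-sorting artefacts,
  OFF-centre subpopulations, contrast dependence, retinogeniculate
  correlations, adaptation within trials, and any cortical feedback or
  inhibition. Passing tests show the pipeline's internal consistency under
  the generator's assumptions, not fidelity to any particular animal.
* **Tuning-width response to jitter.** In this calibrated model the fitted
  HWHH *narrows* by ≈ 2–3° from 6 ms to 40 ms of minimum jitter (with a
  small uptick from 33 to 40 ms), whereas cortical recordings motivate an
  increase of ≈ 1.5° by 35 ms. The discrepancy traces to low-jitter
  saturation of the peak response in the sufficient-firing regime (the
  volley-driven top of the tuning curve flattens, widening the fit at high
  synchrony). The corresponding acceptance check is left failing rather
  than re-tuned.
* **Location of the efficiency optimum.** The measured IPS curve has a
  broad, flat top: it rises from 6 ms, stays within a few percent of its
  maximum between roughly 10 and 26 ms, and falls steeply past 30 ms. The
  measured argmax falls in the 10–20 ms range, but the quadratic-fit vertex
  lands at 18–22 ms across seeds rather than ~16 ms: the elevated
  moderate-jitter information produced by the width narrowing above drags
  the fitted parabola rightward. The corresponding acceptance comparison is
  reported as measured.
* **Narrow-width efficiency.** For pathologically narrow tuning (HWHH ≈ 2–4°)
  the measured IPS optimum stays interior (~18–25 ms) instead of pinning to
  the lowest simulated jitter; the same low-jitter peak-count saturation
  prevents IPS from growing without bound as synchrony increases. Wide
  tuning widths behave as expected (optima in the 10–20 ms range).
* **Mean–variance slope dispersion.** The pooled variance-on-mean slope is
  centred on ≈ 3 but inherits the sampling luck of the ~30 recorded session
  gains in any single run (seed-to-seed spread ≈ ±0.6 at working scale).
* The estimator SD is a lower bound under the unbiased-estimator
  assumption; only relative comparisons across synchrony conditions are
  meaningful, which is how the results are framed.
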