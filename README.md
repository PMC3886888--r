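# thalsync

Simulation and decoding pipeline for the role of **thalamic population
synchrony** in the emergence of cortical orientation selectivity.

Individual LGN relay cells respond to a drifting sinusoidal grating at
nearly the same rate whatever the grating's direction — yet the layer 4
cortical neuron they converge on is sharply orientation tuned. `thalsync`
implements, end to end, the feedforward explanation in which the tuning
signal is carried by *spike timing*: the ~30 convergent LGN receptive
fields form an elongated cluster, so a grating drifting perpendicular to
the cluster's major axis excites all of them in near-synchronous volleys,
while other directions spread their response latencies across the grating
period. A leaky integrate-and-fire cortical neuron with a 2 ms membrane
time constant converts that synchrony into orientation-tuned firing, and
Fisher-information analysis of its spike counts quantifies how much
orientation information each cortical spike carries as a function of the
thalamic timing jitter.

The pipeline, module by module:

1. **Synthetic LGN templates** — overlapping ON-centre receptive fields and
   an event-based spike generator for drifting gratings (0.5 cyc/deg, 5 Hz:
   one sharp response event per cycle plus a decaying tail; mean rates
   16–28 Hz, direction-insensitive; supra-Poisson trial counts from a
   shared per-trial session gain).
2. **Population filling** — duplication and translation of the templates to
   a 30-member convergent population under the receptive-field-separation
   (RFCD) distribution on [0.4, 2.0], with each spatial shift converted to
   a response latency `d * cos(phi) * f_s / f_t`.
3. **Timing jitter** — population synchrony measured as the width of a
   Gaussian fitted to the pooled spike-time autocorrelation on ±100 ms:
   `delta_t = delta_r / 2`, where `delta_r` is the lag at which the
   normalised fit falls to `exp(-1)`.
4. **Controlled synchrony + cortical model** — orientation-dependent
   Gaussian timing noise `sigma(theta)` (minimum `sigma_min` at the
   preferred orientation, swept 6–40 ms) driving a forward-Euler LIF
   neuron (`tau_m dV/dt = -(V - E_rest) + R_m I_syn`, dt = 0.05 ms) through
   summed exponential EPSCs.
5. **Decoding** — Gaussian tuning fits and HWHH, spike-count mean–variance
   statistics, Poisson response models, Fisher information `J(theta)`
   (expectation form and closed form `lambda'^2/lambda`), the Cramér-Rao
   estimator SD `1/sqrt(J_peak)`, and information per spike
   `IPS = J_peak / peak count`, whose optimum over `sigma_min` is the
   headline quantity.

The models, parameters, numerical choices, and known limitations are
documented in `vignettes/thalamic-synchrony-methods.Rmd`.

## Worked example

```r
library(thalsync)

config <- desk_config(seed = 1)
world  <- build_world(config)          # templates, trains, filled population

# population timing jitter at the asynchronous and preferred directions
jit <- jitter_tuning_curve(world$templates, world$trains, seq(0, 315, 45),
                           n_refills = 20, rng_seed = 2)
round(1000 * jit$curve$delta_t_s, 1)
#> [1] 93.2 60.7 23.0 81.0 90.9 65.2 23.5 69.3
jit$dip$width_deg
#> [1] 30.7847

# cortical response at high synchrony vs the orthogonal direction
pref <- run_condition(world$layout, profile = jitter_profile(0.006),
                      direction_deg = 90, n_trials = 25, rng_seed = 3,
                      bank = world$bank)
orth <- run_condition(world$layout, profile = jitter_profile(0.006),
                      direction_deg = 0, n_trials = 25, rng_seed = 4,
                      bank = world$bank)
c(pref = mean(pref$counts$spike_count), orth = mean(orth$counts$spike_count))
#>  pref  orth
#> 31.40  1.48
```

The jitter curve dips from the ~100 ms asynchronous ceiling to ~23 ms at
the synchrony-preferred directions (90°/270°), with a ~31° wide dip; the
same population drives the cortical cell at ~31 spikes/trial at the
preferred direction versus ~1.5 at the orthogonal one.

The full experiment — jitter sweep, cortical simulation, tuning and
information analysis, width sweep — is organised as numbered drivers under
`analysis/` (each writes tidy tables under `results/`), or in one call:

```r
res <- run_experiment(desk_config(seed = 1), "results/run1")
res$summary
```

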