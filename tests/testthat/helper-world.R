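# Shared fixtures, built once per test run and cached. All fixtures are
# generated in code from fixed seeds; sizes are reduced working scales of the
# default experiment.

.ts_cache <- new.env(parent = emptyenv())

ts_memo <- function(key, expr) {
  if (!exists(key, envir = .ts_cache)) assign(key, expr, envir = .ts_cache)
  get(key, envir = .ts_cache)
}

ts_config <- function() desk_config(seed = 101)

ts_world <- function() ts_memo("world", build_world(ts_config()))

# multi-trial jitter tuning curve at 100 refills (shared by the
# synchrony acceptance checks)
ts_jitter_curve <- function() ts_memo("jitter_curve", {
  w <- ts_world()
  jitter_tuning_curve(w$templates, w$trains, seq(0, 315, 45),
                      n_refills = 100, rng_seed = 202)
})

# cortical sweep over the full sigma_min grid (shared by the tuning-info
# acceptance checks); 100 trials per condition as in the working profile
ts_sweep_counts <- function() ts_memo("sweep_counts", {
  w <- ts_world()
  run_tuning_sweep(w, ts_config(), n_trials = 100)
})

# small synthetic Poisson counts from a known Gaussian tuning curve
ts_gauss_counts <- function(amp = 8, sd_deg = 13, baseline = 0.5,
                            n_trials = 60, step = 5, seed = 7) {
  set.seed(seed)
  th <- seq(0, 180 - step, by = step)
  lam <- baseline + amp * exp(-(th - 90)^2 / (2 * sd_deg^2))
  data.frame(direction_deg = rep(th, each = n_trials),
             spike_count = rpois(length(th) * n_trials, rep(lam, each = n_trials)))
}
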