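# EPSC superposition and forward-Euler integrate-and-fire dynamics.

test_that("EPSC kernel has unit-amplitude onset and exponential decay", {
  cfg <- lif_config(i0 = 0.06, tau_epsc = 3)
  cur <- synaptic_current(0, cfg, 0.02)
  expect_equal(cur$i_syn_na[1], 0.06)
  idx3ms <- 1 + 3 / cfg$dt
  expect_equal(cur$i_syn_na[idx3ms], 0.06 / exp(1), tolerance = 1e-9)
  # no spikes -> identically zero
  expect_true(all(synaptic_current(numeric(0), cfg, 0.01)$i_syn_na == 0))
  # linear superposition: coincident spikes double the current everywhere
  one <- synaptic_current(0.005, cfg, 0.02)$i_syn_na
  two <- synaptic_current(c(0.005, 0.005), cfg, 0.02)$i_syn_na
  expect_equal(two, 2 * one, tolerance = 1e-12)
})

test_that("membrane at rest stays at rest and obeys the closed form", {
  cfg <- lif_config()
  tr0 <- integrate_lif(rep(0, 4001), cfg)
  expect_true(all(tr0$v_mv == cfg$e_rest))
  expect_equal(tr0$n_spikes, 0)

  # subthreshold step: V(t) = E + R*I*(1 - exp(-t/tau)), relative error
  # below 0.1% at dt = 0.05 ms
  icon <- 0.1  # nA; R*I = 5.2 mV, below threshold gap
  tr <- integrate_lif(rep(icon, 20001), cfg)
  tt <- (seq_along(tr$v_mv) - 1) * cfg$dt
  v_exact <- cfg$e_rest + cfg$r_m * icon * (1 - exp(-tt / cfg$tau_m))
  expect_lt(max(abs(tr$v_mv - v_exact) / abs(v_exact)), 0.001)
  expect_equal(tr$n_spikes, 0)
})

test_that("synchronous volleys fire the cell; refractoriness is absolute", {
  cfg <- lif_config()
  r <- lif_response(rep(0.010, 30), cfg, 0.05)
  expect_gte(r$n_spikes, 1)
  expect_lt(r$spike_times_s[1] - 0.010, 0.005)

  # dense drive: many spikes, every interspike interval >= t_refract
  set.seed(51)
  drive <- sort(runif(3000, 0, 0.5))
  rr <- lif_response(drive, cfg, 0.5, return_trace = TRUE)
  expect_gt(rr$n_spikes, 10)
  expect_true(all(diff(rr$spike_times_s) >= cfg$t_refract / 1000 - 1e-9))
  # spike samples sit at v_spike; the following sample is clamped at reset
  idx <- round(rr$spike_times_s * 1000 / cfg$dt) + 1
  expect_true(all(rr$v_mv[idx] == cfg$v_spike))
  expect_true(all(rr$v_mv[idx + 1] == cfg$v_reset))
})

test_that("halving the Euler step changes condition counts by under 2%", {
  w <- ts_world()
  counts <- sapply(1:30, function(r) {
    pop <- controlled_population_input(w$layout, w$bank,
                                       jitter_profile(0.014), 90,
                                       rng_seed = 700 + r)
    c(lif_response(pop, lif_config(), 1)$n_spikes,
      lif_response(pop, lif_config(dt = 0.025), 1)$n_spikes)
  })
  m <- rowMeans(counts)
  expect_lt(abs(m[1] - m[2]) / m[1], 0.02)
})

test_that("preferred-direction drive dominates the orthogonal direction", {
  w <- ts_world()
  pr <- jitter_profile(0.006)
  pref <- run_condition(w$layout, profile = pr, direction_deg = 90,
                        n_trials = 25, rng_seed = 52, bank = w$bank)
  orth <- run_condition(w$layout, profile = pr, direction_deg = 0,
                        n_trials = 25, rng_seed = 53, bank = w$bank)
  expect_gt(mean(pref$counts$spike_count),
            3 * mean(orth$counts$spike_count))
  # mean count decreases as sigma_min grows
  hi <- run_condition(w$layout, profile = jitter_profile(0.040),
                      direction_deg = 90, n_trials = 25, rng_seed = 54,
                      bank = w$bank)
  expect_gt(mean(pref$counts$spike_count),
            mean(hi$counts$spike_count))
})

test_that("trial-averaged membrane potential is modulated at the drift rate", {
  w <- ts_world()
  res <- run_condition(w$layout, profile = jitter_profile(0.010),
                       direction_deg = 90, n_trials = 30, rng_seed = 55,
                       bank = w$bank, mean_trace = TRUE)
  v <- res$mean_v
  dt_s <- lif_config()$dt / 1000
  # power spectrum of the mean trace peaks at the 5 Hz temporal frequency
  vz <- v - mean(v)
  sp <- Mod(fft(vz))^2
  freqs <- (seq_along(vz) - 1) / (length(vz) * dt_s)
  band <- freqs > 1 & freqs < 50
  expect_equal(freqs[band][which.max(sp[band])], 5, tolerance = 0.3)
})

test_that("EPSC efficacy sweeps span the three firing regimes", {
  w <- ts_world()
  labs <- sapply(c(0.02, 0.06, 0.2), function(i0) {
    rc <- run_condition(w$layout, profile = jitter_profile(0.014),
                        direction_deg = 90, n_trials = 20,
                        cfg = lif_config(i0 = i0), rng_seed = 56,
                        bank = w$bank)
    classify_firing_regime(mean(rc$counts$spike_count))
  })
  expect_equal(labs, c("impoverished", "sufficient", "strong"))
})

test_that("invalid configurations are rejected", {
  expect_error(lif_config(dt = 3))            # dt >= tau_m
  expect_error(lif_config(v_reset = -50))     # reset above threshold
  expect_error(lif_config(t_refract = -1))
})
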