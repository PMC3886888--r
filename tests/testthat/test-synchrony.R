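# Pooled autocorrelation, jitter estimation, and controlled jitter injection.

test_that("pooled autocorrelation handles elementary spike patterns", {
  # two spikes: mass only at +/-50 ms
  ac <- pooled_autocorrelation(c(0.10, 0.15))
  nz <- ac$lags[ac$counts > 0]
  expect_equal(sort(nz), c(-0.05, 0.05), tolerance = 1e-9)
  # perfectly synchronous spikes: all mass in the zero-lag bin
  ac2 <- pooled_autocorrelation(rep(0.3, 20))
  expect_equal(ac2$lags[ac2$counts > 0], 0)
  # exact symmetry by antisymmetry of pairwise differences
  set.seed(41)
  ac3 <- pooled_autocorrelation(runif(300))
  expect_identical(ac3$counts, rev(ac3$counts))
  expect_error(pooled_autocorrelation(0.1), "at least 2")
})

test_that("periodic event trains produce satellite peaks at the period", {
  set.seed(42)
  ev <- rep((0:4) * 0.2 + 0.05, each = 30) + rnorm(150, 0, 0.005)
  ac <- pooled_autocorrelation(ev)
  in_win <- function(lag, w = 0.01) max(ac$counts[abs(ac$lags - lag) <= w])
  expect_gt(in_win(0.2), 10 * in_win(0.1))
  expect_gt(in_win(-0.2), 10 * in_win(-0.1))
})

test_that("estimate_jitter recovers injected Gaussian timing SD", {
  for (sig in c(5, 10, 20, 40) / 1000) {
    set.seed(43)
    events <- (0:4) * 0.2 + 0.05
    t <- as.vector(sapply(1:30, function(i)
      rep(events, 4) + rnorm(20, 0, sig)))
    est <- estimate_jitter(pooled_autocorrelation(t), period = 0.2)
    expect_lt(abs(est$delta_t - sig) / sig, 0.10)
    expect_equal(est$delta_t, est$delta_r / 2)
  }
})

test_that("asynchronous and synchronous limits hit the window bounds", {
  set.seed(44)
  est <- estimate_jitter(pooled_autocorrelation(runif(600, 0, 1),
                                                duration = 1),
                         period = 0.2)
  expect_true(est$censored)
  expect_equal(est$delta_t, 0.1)
  # zero-jitter synchronous events collapse to the bin-width floor
  t0 <- rep((0:4) * 0.2 + 0.05, each = 30)
  est0 <- estimate_jitter(pooled_autocorrelation(t0), period = 0.2)
  expect_lt(est0$delta_t, 0.005)
})

test_that("sigma(theta) profile has the required dip geometry", {
  pr <- jitter_profile(sigma_min = 0.01, sigma_max = 0.08, width_deg = 30,
                       theta_pref = 90)
  expect_equal(sigma_at(pr, 90), 0.01)
  expect_equal(sigma_at(pr, 270), 0.01)   # dip repeats at theta_pref + 180
  expect_equal(sigma_at(pr, 13), sigma_at(pr, 13 + 360))
  expect_gt(sigma_at(pr, 0), 0.07)
  # flat control condition
  fl <- jitter_profile(sigma_min = 0.02, sigma_max = 0.02)
  expect_equal(sigma_at(fl, seq(0, 350, 10)), rep(0.02, 36))
  expect_error(jitter_profile(sigma_min = 0), "sigma_min")
})

test_that("controlled jitter reduces to the template in the noise-free limit", {
  w <- ts_world()
  # zero latencies: collapse member positions onto the donor centre
  lay <- w$layout
  lay$members$center_az <- lay$templates$center_az[1]
  lay$members$center_el <- lay$templates$center_el[1]
  pop <- apply_controlled_jitter(w$donor_trial, lay,
                                 jitter_profile(1e-6, 1e-6), 90,
                                 rng_seed = 45)
  for (id in unique(pop$neuron_id))
    expect_equal(pop$time_s[pop$neuron_id == id], sort(w$donor_trial),
                 tolerance = 1e-4)
})

test_that("measured jitter grows monotonically with injected sigma_min", {
  w <- ts_world()
  stim <- grating_stimulus(90)
  lay <- w$layout
  # zero latencies isolate the injected noise
  lay$members$center_az <- lay$templates$center_az[1]
  lay$members$center_el <- lay$templates$center_el[1]
  dt <- sapply(c(6, 12, 20, 30, 40) / 1000, function(sg) {
    pop <- apply_controlled_jitter(w$donor_trial, lay,
                                   jitter_profile(sg, 0.1), 90,
                                   rng_seed = 46)
    estimate_jitter(pooled_autocorrelation(pop, duration = 1),
                    period = 0.2)$delta_t
  })
  expect_true(all(diff(dt) > -0.001))
})

test_that("single-neuron populations show no orientation-tuned synchrony", {
  tpl <- make_template_population(1, rng_seed = 47)
  trains <- simulate_lgn_directions(tpl, seq(0, 315, 45), cycle_psth(), 10,
                                    rng_seed = 48)
  jc <- jitter_tuning_curve(tpl, trains, seq(0, 315, 45), target_size = 1,
                            n_refills = 8, rng_seed = 49)
  dtv <- jc$curve$delta_t_s
  pref <- seq(0, 315, 45) %% 180 == 90
  # no systematic dip at the would-be preferred directions
  expect_lt((mean(dtv[!pref]) - mean(dtv[pref])) / mean(dtv[!pref]), 0.25)
})

test_that("trial bank and resampled input preserve counts and bounds", {
  w <- ts_world()
  expect_equal(length(w$bank), 5)
  expect_true(all(lengths(w$bank) == ts_config()$generator$n_trials))
  pop <- controlled_population_input(w$layout, w$bank, jitter_profile(0.01),
                                     90, rng_seed = 50, pooled = FALSE)
  expect_true(all(pop$time_s >= 0 & pop$time_s <= 1))
  expect_equal(sort(unique(pop$neuron_id)), 1:30)
  pooled <- controlled_population_input(w$layout, w$bank,
                                        jitter_profile(0.01), 90,
                                        rng_seed = 50)
  expect_false(is.unsorted(pooled))
  expect_equal(length(pooled), nrow(pop))
})
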