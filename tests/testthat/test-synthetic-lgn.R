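# Template generation and the event-based grating response generator.

test_that("template layouts respect overlap geometry and are reproducible", {
  tpl <- make_template_population(5, rng_seed = 3)
  expect_equal(nrow(tpl), 5)
  expect_true(all(pairwise_separations(tpl) < 2.0))
  expect_true(all(tpl$diameter > 0))
  expect_identical(tpl, make_template_population(5, rng_seed = 3))
  expect_false(identical(tpl$center_el,
                         make_template_population(5, rng_seed = 4)$center_el))

  single <- make_template_population(1, rng_seed = 1)
  expect_equal(nrow(single), 1)
  expect_length(pairwise_separations(single), 0)

  too_wide <- template_geometry(center_span_az = 4, diameter = 1)
  expect_error(make_template_population(5, too_wide), "overlap impossible")
})

test_that("mean rates sit in the physiological band, insensitive to direction", {
  tpl <- make_template_population(1, rng_seed = 5)
  psth <- cycle_psth()
  rates <- sapply(seq(0, 315, 45), function(th) {
    tr <- simulate_lgn_responses(tpl, grating_stimulus(th), psth,
                                 n_trials = 400,
                                 rng_seed = 600 + th)
    nrow(tr) / 400
  })
  grand <- mean(rates)
  expect_lt(abs(grand - psth$rate_mean) / psth$rate_mean, 0.2)
  expect_lt(max(rates) / min(rates), 1.15)
  expect_error(cycle_psth(rate_mean = 40), "physiological band")
})

test_that("spike trains are sorted, bounded, and periodic at the drift rate", {
  tpl <- make_template_population(3, rng_seed = 8)
  stim <- grating_stimulus(45)
  tr <- simulate_lgn_responses(tpl, stim, cycle_psth(), n_trials = 20,
                               rng_seed = 9)
  expect_true(all(tr$time_s >= 0 & tr$time_s <= stim$duration))
  by_unit <- split(tr$time_s, list(tr$neuron_id, tr$trial))
  expect_true(all(vapply(by_unit, function(t) !is.unsorted(t), logical(1))))

  # pooled response has one event per cycle: autocorrelation peaks at the
  # stimulus period, and mean events per trial equals duration * f_t
  tpl1 <- make_template_population(1, rng_seed = 10)
  big <- simulate_lgn_responses(tpl1, grating_stimulus(0), cycle_psth(),
                                n_trials = 400, rng_seed = 11)
  ac <- pooled_autocorrelation(big$time_s, bin_width = 0.002)
  near <- function(lag) which(abs(ac$lags - lag) < 0.01)
  away <- which(abs(abs(ac$lags) - 0.1) < 0.01)
  expect_gt(max(ac$counts[near(0.2)]), 2 * max(ac$counts[away]))
  expect_gt(max(ac$counts[near(-0.2)]), 2 * max(ac$counts[away]))
})

test_that("zero event timescale collapses spikes onto the event phases", {
  tpl <- make_template_population(1, rng_seed = 12)
  psth <- cycle_psth(event_timescale = 0, tail_fraction = 0,
                     trial_gain_cv = 0)
  tr <- simulate_lgn_responses(tpl, grating_stimulus(0), psth, n_trials = 5,
                               rng_seed = 13)
  # all spikes at exactly 5 distinct per-cycle event times
  expect_lte(length(unique(round(tr$time_s, 9))), 5)
  expect_error(simulate_lgn_responses(tpl, grating_stimulus(0),
                                      psth, 0), "n_trials")
})

test_that("identical seeds reproduce identical spike train sets", {
  tpl <- make_template_population(4, rng_seed = 14)
  a <- simulate_lgn_directions(tpl, c(0, 90), cycle_psth(), 5, rng_seed = 15)
  b <- simulate_lgn_directions(tpl, c(0, 90), cycle_psth(), 5, rng_seed = 15)
  expect_identical(a, b)
})
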