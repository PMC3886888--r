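# Population filling under the separation model and shift-latency geometry.

test_that("fill_population builds a bounded 30-member population", {
  tpl <- make_template_population(5, rng_seed = 21)
  layout <- fill_population(tpl, rng_seed = 22)
  m <- layout$members
  expect_equal(nrow(m), 30)
  expect_true(all(m$center_az >= layout$region$az[1] &
                    m$center_az <= layout$region$az[2]))
  expect_true(all(m$center_el >= layout$region$el[1] &
                    m$center_el <= layout$region$el[2]))
  seps <- pairwise_separations(m)
  expect_true(all(seps <= 2.0))
  expect_true(all(seps >= 0.4 * (1 - layout$overlap_tol) - 1e-12))
  expect_equal(layout$theta_pref, 90)
  # determinism
  layout2 <- fill_population(tpl, rng_seed = 22)
  expect_identical(layout$members, layout2$members)
})

test_that("identity fill returns the templates unchanged", {
  tpl <- make_template_population(4, rng_seed = 23)
  layout <- fill_population(tpl, target_size = 4, rng_seed = 24)
  expect_equal(layout$members$center_az, tpl$center_az)
  expect_true(all(layout$members$shift_az == 0))
})

test_that("anchored separations follow the separation model (large region)", {
  # a single template in a region wide enough that truncation is negligible
  tpl <- make_template_population(1, rng_seed = 25)
  sm <- separation_model()
  layout <- fill_population(tpl, sm, target_size = 600, rng_seed = 26,
                            region = list(az = c(-60, 60), el = c(-60, 60)))
  s <- layout$members$anchored_sep
  s <- s[!is.na(s)]
  ref <- local({set.seed(27); sm$sample(20000)})
  expect_gt(suppressWarnings(stats::ks.test(s, ref))$p.value, 0.01)
  # tabulated density override is honoured
  tab <- separation_model(density_table = data.frame(
    x = seq(0.4, 2, 0.1), density = rep(1, 17)))
  expect_equal(tab$density(1.2), tab$density(0.6), tolerance = 1e-6)
})

test_that("fill fails with a diagnostic when constraints are unsatisfiable", {
  tpl <- make_template_population(2, rng_seed = 28)
  expect_error(
    fill_population(tpl, target_size = 200, rng_seed = 29,
                    max_proposals = 400, max_restarts = 2),
    "population fill failed")
})

test_that("shift latency matches the drifting-sinusoid phase oracle", {
  # brute force: peak times of cos(2*pi*(f_s * x - f_t * t)) at two points
  peak_time <- function(x, f_s = 0.5, f_t = 5) {
    tt <- seq(0, 1 / f_t, by = 1e-5)
    tt[which.max(cos(2 * pi * (f_s * x - f_t * tt)))]
  }
  stim <- grating_stimulus(0)
  rf_a <- list(center_az = 0, center_el = 0)
  rf_b <- list(center_az = 1, center_el = 0)
  expect_equal(shift_latency(rf_a, rf_b, stim),
               peak_time(1) - peak_time(0), tolerance = 1e-4)
  expect_equal(shift_latency(rf_a, rf_b, stim), 0.1, tolerance = 1e-9)
  # separation parallel to the grating edge gives zero latency
  rf_c <- list(center_az = 0, center_el = 3)
  expect_equal(shift_latency(rf_a, rf_c, stim), 0, tolerance = 1e-12)
  # two degrees -> one full period, not wrapped
  rf_d <- list(center_az = 2, center_el = 0)
  expect_equal(shift_latency(rf_a, rf_d, stim), 0.2, tolerance = 1e-9)
})

test_that("latency is linear in separation and cosine in angle", {
  stim <- grating_stimulus(0)
  ds <- seq(0.2, 2, 0.2)
  lat_d <- sapply(ds, function(d)
    shift_latency(list(center_az = 0, center_el = 0),
                  list(center_az = d, center_el = 0), stim))
  expect_equal(lat_d, 0.1 * ds, tolerance = 1e-12)
  phis <- seq(0, pi / 2, length.out = 10)
  lat_phi <- sapply(phis, function(p)
    shift_latency(list(center_az = 0, center_el = 0),
                  list(center_az = cos(p), center_el = -sin(p)),
                  grating_stimulus(0)))
  expect_equal(lat_phi, 0.1 * cos(phis), tolerance = 1e-12)
  # opposite drift directions flip the sign
  for (th in c(0, 45, 90, 130)) {
    l1 <- shift_latency(list(center_az = 0, center_el = 0),
                        list(center_az = 0.7, center_el = 0.2),
                        grating_stimulus(th))
    l2 <- shift_latency(list(center_az = 0, center_el = 0),
                        list(center_az = 0.7, center_el = 0.2),
                        grating_stimulus(th + 180))
    expect_equal(l1, -l2, tolerance = 1e-12)
  }
})

test_that("assembled population spikes carry the shift latencies", {
  tpl <- make_template_population(2, rng_seed = 31)
  trains <- simulate_lgn_directions(tpl, c(0, 90), cycle_psth(), 6,
                                    rng_seed = 32)
  stim <- grating_stimulus(0)
  # identity: single-template layout with zero shift replays the trial
  layout1 <- fill_population(tpl, target_size = 2, rng_seed = 33)
  pop <- assemble_population_spikes(layout1, trains, stim, rng_seed = 34)
  prov <- attr(pop, "assigned_trial")
  src <- trains[trains$neuron_id == 1 & trains$direction_deg == 0 &
                  trains$trial == prov$trial[1], ]
  expect_equal(pop$time_s[pop$neuron_id == 1], src$time_s)
  expect_true(all(pop$time_s >= 0 & pop$time_s <= stim$duration))

  # two members sharing a trial at a 0.1 s latency offset: the
  # cross-correlogram of their trains peaks at the 0.1 s lag (equivalently
  # -0.1 s, half the 0.2 s stimulus period, after periodic wrapping)
  one <- make_template_population(1, rng_seed = 35)
  members <- data.frame(member_id = 1:2, template_id = 1L,
                        center_az = one$center_az + c(0, 1),
                        center_el = one$center_el, diameter = one$diameter,
                        polarity = "ON", shift_az = c(0, 1), shift_el = 0,
                        anchored_sep = NA_real_)
  lay <- structure(list(members = members, templates = one,
                        region = list(az = c(-1, 2), el = c(-1, 1)),
                        theta_pref = 90, overlap_tol = 0.8),
                   class = "population_layout")
  tr1 <- simulate_lgn_responses(one, stim, cycle_psth(), 1, rng_seed = 37)
  pop2 <- assemble_population_spikes(lay, tr1, stim, rng_seed = 38)
  a <- pop2$time_s[pop2$neuron_id == 1]
  b <- pop2$time_s[pop2$neuron_id == 2]
  d <- as.vector(outer(b, a, "-"))
  h <- hist(d[abs(d) <= 0.19], breaks = seq(-0.19, 0.19, 0.005),
            plot = FALSE)
  expect_lt(abs(abs(h$mids[which.max(h$counts)]) - 0.1), 0.011)
})
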