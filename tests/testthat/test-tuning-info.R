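# Tuning-curve fits, mean-variance statistics, Fisher information, and the
# efficiency analysis.

test_that("fit_tuning recovers a known Gaussian tuning curve", {
  counts <- ts_gauss_counts(amp = 8, sd_deg = 13, baseline = 0.5,
                            n_trials = 150)
  tun <- fit_tuning(counts)
  expect_false(tun$flat)
  expect_lt(abs(tun$fit[["sd"]] - 13) / 13, 0.05)
  expect_equal(tun$hwhh_deg, tun$fit[["sd"]] * sqrt(2 * log(2)))
  expect_equal(tun$theta_peak, 90, tolerance = 6)

  # constant counts: flagged flat, HWHH undefined
  flat <- data.frame(direction_deg = rep(seq(0, 175, 5), each = 10),
                     spike_count = 7L)
  tf <- fit_tuning(flat)
  expect_true(tf$flat)
  expect_true(is.na(tf$hwhh_deg))
  expect_error(response_model(tf), "flat")
  expect_error(fit_tuning(counts[counts$direction_deg == 0, ]), "distinct")
})

test_that("mean-variance slope calibrates to 1 for Poisson, 0 for constant", {
  counts <- ts_gauss_counts(amp = 15, sd_deg = 20, baseline = 1,
                            n_trials = 250, seed = 8)
  mv <- mean_variance_relation(counts)
  expect_lt(abs(mv$slope - 1), 0.15)
  det <- data.frame(direction_deg = rep(seq(0, 175, 5), each = 10),
                    spike_count = rep(seq(2, 37, 1), each = 10))
  expect_lt(abs(mean_variance_relation(det)$slope), 1e-9)
  expect_error(mean_variance_relation(det[1:10, ]), "3")
})

test_that("Fisher information vanishes for a flat response model", {
  mod <- structure(list(theta_deg = 0:180, offset_deg = -90:90,
                        lambda_hat = rep(5, 181), grid_step = 1),
                   class = "response_model")
  fi <- fisher_information(mod)
  expect_true(all(fi$j_closed == 0))
  expect_lt(max(fi$j_expectation), 1e-20)
})

test_that("expectation-form Fisher information matches the Poisson closed form", {
  for (amp in c(4, 8)) for (wd in c(10, 13, 20)) {
    off <- -90:90
    lam <- 2 + amp * exp(-(off - 0)^2 / (2 * wd^2))
    mod <- structure(list(theta_deg = off + 90, offset_deg = off,
                          lambda_hat = lam, grid_step = 1),
                     class = "response_model")
    fi <- fisher_information(mod, n_max = 200)
    keep <- fi$j_closed > 0.01 * max(fi$j_closed) &
      seq_along(off) > 3 & seq_along(off) < length(off) - 2
    rel <- abs(fi$j_expectation[keep] - fi$j_closed[keep]) /
      fi$j_closed[keep]
    expect_lt(max(rel), 0.01)
    # information peaks on the tuning flank, not at the peak
    expect_gt(abs(fi$theta_deg[which.max(fi$j_expectation)] - 90), 5)
  }
})

test_that("efficiency analysis enforces the Cramer-Rao arithmetic", {
  set.seed(9)
  counts <- do.call(rbind, lapply(c(6, 15, 25, 40) / 1000, function(sg) {
    amp <- 30 * exp(-sg / 0.02)
    d <- ts_gauss_counts(amp = amp, sd_deg = 13, baseline = 1,
                         n_trials = 80, seed = round(sg * 1e5))
    d$sigma_min_s <- sg
    d
  }))
  eff <- efficiency_analysis(counts)
  bl <- eff$by_level
  expect_equal(bl$est_sd_deg * sqrt(bl$j_peak), rep(1, 4),
               tolerance = 1e-12)
  expect_true(all(is.finite(bl$ips)))
  # trivial Cramer-Rao arithmetic: J = 4 deg^-2 -> SD = 0.5 deg
  expect_equal(1 / sqrt(4), 0.5)
  expect_error(efficiency_analysis(counts[counts$sigma_min_s < 0.01, ]),
               "4 sigma_min levels")
})

test_that("width sweep normalises IPS curves and flags boundary optima", {
  # constructed counts where the IPS argmax is known: amplitude rises then
  # falls across levels for width A, monotone for width B
  mk <- function(amps, width_scale) {
    do.call(rbind, lapply(seq_along(amps), function(i) {
      d <- ts_gauss_counts(amp = amps[i], sd_deg = 12, baseline = 2,
                           n_trials = 60, seed = 100 + i + width_scale)
      d$sigma_min_s <- c(6, 15, 25, 40)[i] / 1000
      d$width_scale <- width_scale
      d
    }))
  }
  counts <- rbind(mk(c(10, 18, 10, 5), 1), mk(c(20, 15, 9, 4), 2))
  ws <- width_sweep(counts)
  expect_equal(nrow(ws$per_width), 2)
  for (cu in ws$curves) expect_equal(max(cu$ips_norm, na.rm = TRUE), 1)
  expect_equal(ws$per_width$optimal_sigma_ms[1], 15)
  expect_equal(ws$per_width$optimal_sigma_ms[2], 6)
  expect_false(ws$per_width$interior_peak[2])
})

test_that("Poisson dispersion check accepts Poisson counts", {
  counts <- ts_gauss_counts(amp = 10, sd_deg = 15, baseline = 2,
                            n_trials = 100, seed = 11)
  chk <- poisson_dispersion_check(counts)
  expect_lt(chk$fraction_rejected, 0.10)
  expect_true(all(c("dispersion", "p") %in% names(chk$per_direction)))
})
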