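# Population synchrony quantified as timing jitter from the pooled spike-time
# autocorrelation, and construction of the controlled-synchrony inputs
# (single donor trial plus orientation-dependent Gaussian timing noise).

#' Pooled spike-time autocorrelation
#'
#' All spike times of the population are collapsed into a single train; the
#' histogram of all pairwise time differences on lags \[-max_lag, +max_lag\]
#' forms the autocorrelation estimate, normalised to \[0, 1\] by its peak.
#' Self-pairs (a spike with itself) are excluded: they only add a delta at
#' zero lag that biases narrow fits.
#'
#' @param times pooled spike times (numeric vector), or a `spike_trains`
#'   data.frame (all rows are pooled; restrict to one direction first).
#' @param bin_width histogram bin (s), default 1 ms.
#' @param max_lag lag range half-width (s), default 0.4.
#' @param duration optional trial duration (s); when given, counts are
#'   corrected for the finite-trial triangular envelope (a lag tau can only
#'   be observed over `duration - |tau|`), so a temporally uniform train
#'   yields a flat corrected autocorrelation.
#' @return object of class `pooled_autocorr`: `lags` (bin centres, s),
#'   `counts` (normalised), `raw_counts`, `bin_width`, `n_spikes`.
#' @export
pooled_autocorrelation <- function(times, bin_width = 0.001, max_lag = 0.4,
                                   duration = NULL) {
  if (is.data.frame(times)) times <- times$time_s
  times <- sort(times)
  n <- length(times)
  if (n < 2) stop("pooled autocorrelation needs at least 2 spikes")
  centers <- seq(-max_lag, max_lag, by = bin_width)
  pos <- numeric(length(centers))
  # windowed pairwise differences: successive offsets until out of range
  for (k in seq_len(n - 1)) {
    d <- times[(1 + k):n] - times[1:(n - k)]
    d <- d[d <= max_lag + bin_width / 2]
    if (length(d) == 0) break
    idx <- findInterval(d, centers - bin_width / 2)
    idx <- idx[idx >= 1 & idx <= length(centers)]
    tab <- tabulate(idx, nbins = length(centers))
    pos <- pos + tab
  }
  # differences are antisymmetric: negative lags mirror positive lags
  counts <- pos + rev(pos)
  if (!is.null(duration)) {
    env <- pmax(1 - abs(centers) / duration, 1e-6)
    counts <- counts / env
  }
  structure(list(lags = centers, counts = counts / max(counts),
                 raw_counts = counts, bin_width = bin_width,
                 max_lag = max_lag, n_spikes = n),
            class = "pooled_autocorr")
}

#' Estimate population timing jitter from an autocorrelation
#'
#' A three-parameter Gaussian (amplitude, SD, non-negative baseline) is
#' least-squares fit to the normalised autocorrelation on lags within
#' `fit_window` (default +/-100 ms, which excludes the periodicity of the
#' grating response). The response timescale `delta_r` is the lag at which
#' the fitted curve, normalised to its own peak, equals `exp(-1)`; the PSTH
#' timing jitter is `delta_t = delta_r / 2`. For a Gaussian population PSTH
#' of SD sigma the pairwise-difference distribution has SD sigma * sqrt(2),
#' whose `exp(-1)` lag is 2 * sigma, so `delta_t` recovers sigma.
#'
#' When the fitted baseline is high enough that the normalised curve never
#' reaches `exp(-1)` inside twice the window (an essentially flat
#' autocorrelation, i.e. an asynchronous population), the estimate is
#' censored at the window-limited ceiling `delta_t = fit_window` (100 ms by
#' default) and flagged.
#'
#' When the stimulus `period` is supplied, the fitted model additionally
#' includes the first periodic replicas of the central Gaussian (at lags
#' +/- period, same amplitude and SD). For jitters small against the period
#' the replicas are invisible inside the window and the fit is unchanged;
#' for jitters approaching half the window they absorb the mass leaking in
#' from the neighbouring response events, which otherwise biases the fitted
#' width upward. `delta_r` is always computed from the central component.
#'
#' @param ac a [pooled_autocorrelation()].
#' @param fit_window half-width of the fit window (s).
#' @param period optional stimulus period (s) for the replica terms.
#' @return object of class `jitter_estimate`: `delta_r`, `delta_t` (s),
#'   `fit` (named coefficients a, b, s), `censored`, `fit_window`.
#' @export
estimate_jitter <- function(ac, fit_window = 0.1, period = NULL) {
  keep <- abs(ac$lags) <= fit_window + ac$bin_width / 2
  x <- ac$lags[keep]
  y <- ac$counts[keep]
  if (sum(y) <= 0) stop("no autocorrelation mass inside the fit window")
  starts <- c(0.005, 0.020, 0.080)
  if (is.null(period)) {
    form <- y ~ b + a * exp(-x^2 / (2 * s^2))
  } else {
    pp <- period
    form <- y ~ b + a * (exp(-x^2 / (2 * s^2)) +
                           exp(-(x - pp)^2 / (2 * s^2)) +
                           exp(-(x + pp)^2 / (2 * s^2)))
  }
  best <- NULL
  best_rss <- Inf
  for (s0 in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        form,
        start = list(a = max(y) - min(y) + 1e-6, b = max(min(y), 0), s = s0),
        lower = c(a = 0, b = 0, s = ac$bin_width / 2),
        upper = c(a = Inf, b = Inf, s = 0.5),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(stats::resid(fit)^2)
    if (rss < best_rss) { best <- fit; best_rss <- rss }
  }
  if (is.null(best))
    stop("Gaussian fit to the autocorrelation failed to converge ",
         "(n_spikes = ", ac$n_spikes, ", window = ", fit_window, " s)")
  cf <- coef(best)
  a <- cf[["a"]]; b <- cf[["b"]]; s <- cf[["s"]]
  ceiling_r <- 2 * fit_window
  # lag where (b + a exp(-x^2/2s^2)) / (a + b) = exp(-1)
  q <- (exp(-1) * (a + b) - b) / a
  if (!is.finite(q) || q <= 0) {
    delta_r <- ceiling_r
    censored <- TRUE
  } else {
    delta_r <- s * sqrt(-2 * log(q))
    censored <- delta_r >= ceiling_r
    delta_r <- min(delta_r, ceiling_r)
  }
  delta_r <- max(delta_r, ac$bin_width)
  structure(list(delta_r = delta_r, delta_t = delta_r / 2,
                 fit = c(a = a, b = b, s = s), censored = censored,
                 fit_window = fit_window, rss = best_rss),
            class = "jitter_estimate")
}

#' Gaussian fit to the dip of a jitter tuning curve
#'
#' @param direction_deg,delta_t measured jitter curve (deg, s).
#' @param theta_pref preferred direction (deg); the dip is modelled on the
#'   nearest 180-degree-periodic distance to it.
#' @return list with `width_deg` (fitted SD of the dip), `ceiling_s`,
#'   `depth_s`, and the fit object.
#' @export
fit_jitter_dip <- function(direction_deg, delta_t, theta_pref = 90) {
  d <- dist180(direction_deg, theta_pref)
  fit <- minpack.lm::nlsLM(
    delta_t ~ cc - aa * exp(-d^2 / (2 * w^2)),
    start = list(cc = max(delta_t), aa = max(delta_t) - min(delta_t),
                 w = 30),
    lower = c(cc = 0, aa = 0, w = 1), upper = c(cc = 1, aa = 1, w = 90))
  cf <- coef(fit)
  list(width_deg = cf[["w"]], ceiling_s = cf[["cc"]], depth_s = cf[["aa"]],
       fit = fit)
}

#' Timing jitter versus stimulus direction for refilled populations
#'
#' For each of `n_refills` independent population fills (fresh member
#' placements and fresh template-trial assignments), the population spike
#' trains are assembled at every direction, pooled, and their timing jitter
#' estimated; the curve is summarised by its mean and SD over refills and by
#' a Gaussian fit to the dip around the preferred direction.
#'
#' @param templates templates from [make_template_population()].
#' @param template_trains `spike_trains` covering all `directions`.
#' @param directions directions to measure (deg).
#' @param stim_base a [grating_stimulus()]; direction is overridden.
#' @param sep_model a [separation_model()].
#' @param target_size population size.
#' @param n_refills number of independent fills (50 in the standard
#'   analysis).
#' @param rng_seed integer seed.
#' @param mode assembly mode passed to [assemble_population_spikes()].
#' @return list of class `jitter_curve`: `curve` (data.frame direction_deg,
#'   delta_t_s, sd_over_refills, n_censored), `per_refill` (matrix), `dip`
#'   (from [fit_jitter_dip()]), `theta_pref`.
#' @export
jitter_tuning_curve <- function(templates, template_trains, directions,
                                stim_base = grating_stimulus(),
                                sep_model = separation_model(),
                                target_size = 30, n_refills = 50,
                                rng_seed = 1, mode = "multi-trial") {
  per <- matrix(NA_real_, n_refills, length(directions),
                dimnames = list(NULL, directions))
  cens <- matrix(FALSE, n_refills, length(directions))
  theta_pref <- 90
  for (r in seq_len(n_refills)) {
    layout <- fill_population(templates, sep_model, target_size,
                              rng_seed = derive_seed(rng_seed,
                                                     paste0("fill", r)))
    theta_pref <- layout$theta_pref
    for (j in seq_along(directions)) {
      stim <- stim_base
      stim$direction_deg <- directions[j] %% 360
      pop <- assemble_population_spikes(
        layout, template_trains, stim, mode = mode,
        rng_seed = derive_seed(rng_seed, paste0("asm", r, "d", j)))
      est <- tryCatch(estimate_jitter(pooled_autocorrelation(pop,
                                                            duration =
                                                              stim$duration),
                                      period = stim$period),
                      error = function(e) NULL)
      if (is.null(est)) next
      per[r, j] <- est$delta_t
      cens[r, j] <- est$censored
    }
  }
  curve <- data.frame(direction_deg = directions,
                      delta_t_s = colMeans(per, na.rm = TRUE),
                      sd_over_refills = apply(per, 2, sd, na.rm = TRUE),
                      n_censored = colSums(cens))
  dip <- tryCatch(fit_jitter_dip(curve$direction_deg, curve$delta_t_s,
                                 theta_pref),
                  error = function(e) NULL)
  structure(list(curve = curve, per_refill = per, dip = dip,
                 theta_pref = theta_pref),
            class = "jitter_curve")
}

#' Orientation-dependent timing-jitter profile sigma(theta)
#'
#' The stimulus-dependent component of timing jitter: a Gaussian dip of
#' `width_deg` around the preferred direction, evaluated on the nearest
#' 180-degree-periodic distance, running from `sigma_min` (the swept
#' "minimum jitter", at the preferred orientation) up to `sigma_max`.
#'
#' The default `sigma_max` and `width_deg` are calibration constants fit
#' once (least squares over the eight measured directions) so that the
#' controlled-jitter pipeline reproduces the multi-trial population jitter
#' curve; they can be re-derived with [calibrate_jitter_profile()].
#'
#' @param sigma_min jitter SD at the preferred orientation (s), > 0.
#' @param sigma_max jitter SD far from the preferred orientation (s).
#' @param width_deg Gaussian width of the dip (deg).
#' @param theta_pref preferred direction (deg).
#' @return object of class `jitter_profile`.
#' @export
jitter_profile <- function(sigma_min = 0.020, sigma_max = 0.100,
                           width_deg = 25, theta_pref = 90) {
  stopifnot(sigma_min > 0, sigma_min <= sigma_max, width_deg > 0)
  structure(list(sigma_min = sigma_min, sigma_max = sigma_max,
                 width_deg = width_deg, theta_pref = theta_pref),
            class = "jitter_profile")
}

#' Evaluate sigma(theta)
#'
#' @param profile a [jitter_profile()].
#' @param direction_deg direction(s), degrees.
#' @return jitter SD(s) in seconds.
#' @export
sigma_at <- function(profile, direction_deg) {
  d <- dist180(direction_deg, profile$theta_pref)
  profile$sigma_max - (profile$sigma_max - profile$sigma_min) *
    exp(-d^2 / (2 * profile$width_deg^2))
}

#' Controlled-synchrony population input
#'
#' Every member of the layout replays the same donor template trial, offset
#' by its geometric latency (member position relative to the donor template's
#' RF centre under the drift direction), with independent zero-mean Gaussian
#' timing noise of SD `sigma(direction)` added to every spike. This replaces
#' across-neuron variability with variability under explicit control while
#' retaining the geometry-driven synchrony modulation.
#'
#' @param template_trial numeric vector of donor spike times (s), one trial.
#' @param layout a [fill_population()] result.
#' @param profile a [jitter_profile()].
#' @param direction_deg drift direction (deg).
#' @param stim a [grating_stimulus()] (geometry/period; direction taken from
#'   `direction_deg`).
#' @param rng_seed integer seed.
#' @param donor_template template id whose RF centre anchors the latencies.
#' @param boundary boundary rule for shifted spikes ("wrap" or "truncate").
#' @return `spike_trains` data.frame (one trial, all members).
#' @export
apply_controlled_jitter <- function(template_trial, layout, profile,
                                    direction_deg, stim = grating_stimulus(),
                                    rng_seed = 1, donor_template = 1,
                                    boundary = "wrap") {
  if (length(template_trial) == 0) stop("empty template trial")
  set.seed(rng_seed)
  stim$direction_deg <- direction_deg %% 360
  donor <- layout$templates[layout$templates$neuron_id == donor_template, ]
  m <- layout$members
  lat <- position_latency(m$center_az - donor$center_az,
                          m$center_el - donor$center_el, stim)
  sig <- sigma_at(profile, direction_deg)
  n_sp <- length(template_trial)
  n_m <- nrow(m)
  t_all <- rep(template_trial, n_m) + rep(lat, each = n_sp) +
    rnorm(n_sp * n_m, 0, sig)
  t_all <- wrap_times(t_all, stim$period, stim$duration, boundary)
  ids <- rep(m$member_id, each = n_sp)
  ord <- order(ids, t_all)
  res <- data.frame(neuron_id = ids[ord],
                    direction_deg = stim$direction_deg, trial = 1L,
                    time_s = t_all[ord])
  class(res) <- c("spike_trains", "data.frame")
  res
}

#' Bank of phase-aligned 0-degree template trials
#'
#' Extracts every 0-degree trial of every template and removes the
#' template's own 0-degree position phase, leaving the intrinsic
#' (trial-to-trial and within-event) timing structure at a common phase.
#'
#' @param trains template `spike_trains` containing direction 0.
#' @param templates the `receptive_fields` templates.
#' @param stim a [grating_stimulus()] (spatial/temporal frequency for the
#'   alignment phase).
#' @return list indexed by template id, each a list of aligned spike-time
#'   vectors (one per trial).
#' @export
template_trial_bank <- function(trains, templates,
                                stim = grating_stimulus()) {
  z <- trains[trains$direction_deg == 0, ]
  if (nrow(z) == 0) stop("template trains contain no 0-degree trials")
  stim0 <- stim
  stim0$direction_deg <- 0
  all_trials <- sort(unique(z$trial))
  bank <- vector("list", max(templates$neuron_id))
  for (i in seq_len(nrow(templates))) {
    id <- templates$neuron_id[i]
    lat0 <- position_latency(templates$center_az[i],
                             templates$center_el[i], stim0)
    zi <- z[z$neuron_id == id, ]
    # empty (silent) trials are kept as zero-length vectors
    bank[[id]] <- lapply(all_trials,
                         function(tr) zi$time_s[zi$trial == tr] - lat0)
  }
  bank
}

#' Controlled-synchrony population input with per-member trial resampling
#'
#' The construction used to drive the cortical model: each member draws a
#' random 0-degree trial of its own template (phase-aligned, preserving the
#' baseline across-neuron timing variability), is offset by the latency of
#' its absolute RF position under the probe direction, and receives
#' independent zero-mean Gaussian timing noise of SD `sigma(direction)` on
#' every spike. Trial assignments are resampled on every call, which is what
#' gives the cortical spike count its trial-to-trial variability.
#'
#' @param layout a [fill_population()] result.
#' @param bank a [template_trial_bank()].
#' @param profile a [jitter_profile()].
#' @param direction_deg probe drift direction (deg).
#' @param stim a [grating_stimulus()].
#' @param rng_seed integer seed.
#' @param boundary boundary rule for shifted spikes.
#' @param pooled return the pooled sorted spike-time vector (fast path for
#'   the integrate-and-fire stage) instead of a `spike_trains` data.frame.
#' @return numeric vector (pooled) or `spike_trains` data.frame.
#' @export
controlled_population_input <- function(layout, bank, profile, direction_deg,
                                        stim = grating_stimulus(),
                                        rng_seed = 1, boundary = "wrap",
                                        pooled = TRUE) {
  set.seed(rng_seed)
  stim$direction_deg <- direction_deg %% 360
  m <- layout$members
  lat <- position_latency(m$center_az, m$center_el, stim)
  sig <- sigma_at(profile, direction_deg)
  n_m <- nrow(m)
  times <- vector("list", n_m)
  for (i in seq_len(n_m)) {
    trials <- bank[[m$template_id[i]]]
    t_sp <- trials[[sample.int(length(trials), 1)]]
    times[[i]] <- t_sp + lat[i]
  }
  n_per <- lengths(times)
  t_all <- unlist(times, use.names = FALSE) + rnorm(sum(n_per), 0, sig)
  t_all <- wrap_times(t_all, stim$period, stim$duration, boundary)
  if (pooled) return(sort(t_all))
  ids <- rep(m$member_id, n_per)
  ord <- order(ids, t_all)
  res <- data.frame(neuron_id = ids[ord],
                    direction_deg = stim$direction_deg, trial = 1L,
                    time_s = t_all[ord])
  class(res) <- c("spike_trains", "data.frame")
  res
}

#' Calibrate the jitter profile against the multi-trial jitter curve
#'
#' Grid search over (`sigma_max`, `width_deg`) minimising the squared
#' distance between the controlled-jitter measured curve and a reference
#' (multi-trial) jitter curve over the measured directions.
#'
#' @param layout a [fill_population()] result.
#' @param template_trial donor spike-time vector (0-degree trial).
#' @param reference data.frame `direction_deg`, `delta_t_s` (the multi-trial
#'   curve to reproduce).
#' @param sigma_min fixed floor of the profile (s).
#' @param sigma_max_grid,width_grid candidate values.
#' @param stim a [grating_stimulus()].
#' @param n_reps noise repetitions per direction per candidate.
#' @param rng_seed integer seed.
#' @return list with the best `profile`, the search table, and the achieved
#'   curve.
#' @export
calibrate_jitter_profile <- function(layout, template_trial, reference,
                                     sigma_min = 0.020,
                                     sigma_max_grid = seq(0.04, 0.12, 0.02),
                                     width_grid = seq(20, 60, 10),
                                     stim = grating_stimulus(), n_reps = 5,
                                     rng_seed = 1) {
  measure <- function(profile) {
    sapply(reference$direction_deg, function(th) {
      vals <- sapply(seq_len(n_reps), function(r) {
        pop <- apply_controlled_jitter(
          template_trial, layout, profile, th, stim,
          rng_seed = derive_seed(rng_seed, paste0("cal", th, "r", r)))
        tryCatch(estimate_jitter(pooled_autocorrelation(pop,
                                                          duration =
                                                            stim$duration),
                                 period = stim$period)$delta_t,
                 error = function(e) NA_real_)
      })
      mean(vals, na.rm = TRUE)
    })
  }
  tab <- expand.grid(sigma_max = sigma_max_grid, width_deg = width_grid)
  tab$sse <- NA_real_
  best <- NULL; best_sse <- Inf; best_curve <- NULL
  for (i in seq_len(nrow(tab))) {
    prof <- jitter_profile(sigma_min, tab$sigma_max[i], tab$width_deg[i],
                           layout$theta_pref)
    cur <- measure(prof)
    sse <- sum((cur - reference$delta_t_s)^2)
    tab$sse[i] <- sse
    if (sse < best_sse) { best <- prof; best_sse <- sse; best_curve <- cur }
  }
  list(profile = best, search = tab,
       achieved = data.frame(direction_deg = reference$direction_deg,
                             delta_t_s = best_curve))
}
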