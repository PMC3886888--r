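# Synthetic LGN templates: receptive-field geometry and event-based spike
# generation to drifting sinusoidal gratings. These stand in for the recorded
# ON-centre X-cell templates that the population-filling method expands.

#' Geometry of the template receptive-field cluster
#'
#' Describes the elongated cluster of overlapping ON-centre receptive fields.
#' Sizes are in degrees of visual angle. The defaults are calibration
#' constants chosen once so that the multi-trial population timing-jitter
#' curve shows its empirically observed shape (asynchronous ceiling near
#' 100 ms, preferred-orientation floor near 24 ms, dip width near 31 degrees)
#' for a 0.5 cycles/degree, 5 Hz grating; see the methods vignette.
#'
#' @param center_span_az horizontal extent of RF centres (deg).
#' @param center_span_el vertical extent of RF centres (deg).
#' @param diameter RF centre diameter (20%-of-peak contour circle, deg).
#' @param polarity "ON" or "OFF"; populations are single-polarity.
#' @return object of class `template_geometry`.
#' @export
template_geometry <- function(center_span_az = 1.6, center_span_el = 0.45,
                              diameter = 1.0, polarity = c("ON", "OFF")) {
  polarity <- match.arg(polarity)
  stopifnot(diameter > 0, center_span_az >= 0, center_span_el >= 0)
  structure(list(center_span_az = center_span_az,
                 center_span_el = center_span_el,
                 diameter = diameter, polarity = polarity),
            class = "template_geometry")
}

#' Drifting sinusoidal grating stimulus
#'
#' @param direction_deg drift direction in \[0, 360): 0 = vertical grating
#'   drifting rightward, 90 = horizontal grating drifting downward.
#' @param spatial_freq cycles/degree (> 0).
#' @param temporal_freq Hz (> 0).
#' @param contrast fraction in (0, 1\].
#' @param duration trial length in seconds.
#' @return object of class `grating_stimulus` with derived `period`.
#' @export
grating_stimulus <- function(direction_deg = 0, spatial_freq = 0.5,
                             temporal_freq = 5, contrast = 1, duration = 1) {
  stopifnot(spatial_freq > 0, temporal_freq > 0, duration > 0)
  structure(list(direction_deg = direction_deg %% 360,
                 spatial_freq = spatial_freq, temporal_freq = temporal_freq,
                 contrast = contrast, duration = duration,
                 period = 1 / temporal_freq),
            class = "grating_stimulus")
}

#' Cycle PSTH shape of a template neuron
#'
#' Drifting gratings evoke one dominant response event per cycle with a sharp
#' onset and a decaying tail. The generator draws a Poisson number of spikes
#' per event; each spike is either an "event" spike (Gaussian-jittered around
#' the event time with SD `event_timescale`) or a "tail" spike (exponential
#' delay with time constant `tail_tau`).
#'
#' `event_timescale`, `tail_fraction`, and `tail_tau` are calibration
#' constants fixed once so that the preferred-orientation population timing
#' jitter of the default filled population lands near its physiological value
#' (~24 ms); see the methods vignette.
#'
#' `trial_gain_cv` is the coefficient of variation of a multiplicative
#' per-trial response gain, shared across the simultaneously recorded
#' neurons within a trial. It emulates the slow excitability fluctuations of
#' anesthetized recordings, which make trial spike counts supra-Poisson
#' (trial-count Fano factor `1 + rate_mean * period_total * cv^2`); this
#' across-trial count variability is what the downstream response
#' distributions inherit.
#'
#' @param event_phase fraction of the cycle in \[0,1) at which the event peaks
#'   for a neuron at the visual-field origin.
#' @param event_timescale within-event spike-timing SD (s).
#' @param rate_mean mean firing rate (Hz), inside `rate_band`.
#' @param tail_fraction fraction of spikes falling in the decaying tail.
#' @param tail_tau tail decay time constant (s).
#' @param rate_band physiological band the mean rate must lie in (Hz).
#' @return object of class `cycle_psth`.
#' @export
cycle_psth <- function(event_phase = 0.25, event_timescale = 0.013,
                       rate_mean = 22, tail_fraction = 0.3, tail_tau = 0.040,
                       rate_band = c(16, 28), trial_gain_cv = 0.6) {
  stopifnot(event_phase >= 0, event_phase < 1, event_timescale >= 0,
            tail_fraction >= 0, tail_fraction <= 1, tail_tau > 0,
            trial_gain_cv >= 0)
  if (rate_mean < rate_band[1] || rate_mean > rate_band[2])
    stop("rate_mean ", rate_mean, " Hz outside the physiological band [",
         rate_band[1], ", ", rate_band[2], "] Hz")
  structure(list(event_phase = event_phase,
                 event_timescale = event_timescale, rate_mean = rate_mean,
                 tail_fraction = tail_fraction, tail_tau = tail_tau,
                 rate_band = rate_band, trial_gain_cv = trial_gain_cv),
            class = "cycle_psth")
}

#' Generate template receptive fields
#'
#' Lays out `n_templates` overlapping circular ON-centre receptive fields in
#' an elongated cluster (major axis horizontal by default). Centres are
#' evenly spread along the major axis with random jitter and uniformly
#' scattered along the minor axis. All pairwise centre separations, in units
#' of receptive-field centre diameter (RFCD, centre distance divided by the
#' larger diameter), stay below 2.0.
#'
#' @param n_templates number of template neurons (1-10; 5 by default, as in a
#'   typical simultaneous recording of 5-7 cells).
#' @param geometry a [template_geometry()].
#' @param rng_seed integer seed; identical seeds give identical layouts.
#' @return data.frame of class `receptive_fields` with columns `neuron_id`,
#'   `center_az`, `center_el`, `diameter`, `polarity`.
#' @export
make_template_population <- function(n_templates = 5,
                                     geometry = template_geometry(),
                                     rng_seed = 1) {
  stopifnot(n_templates >= 1, n_templates <= 10)
  span_diag <- sqrt(geometry$center_span_az^2 + geometry$center_span_el^2)
  if (span_diag / geometry$diameter >= 2.0)
    stop("geometry makes overlap impossible: cluster diagonal ",
         round(span_diag / geometry$diameter, 2),
         " RFCD; all pairwise separations must stay below 2.0 RFCD")
  set.seed(rng_seed)
  if (n_templates == 1) {
    az <- 0
  } else {
    az <- seq(-geometry$center_span_az / 2, geometry$center_span_az / 2,
              length.out = n_templates)
    az <- az + runif(n_templates, -0.04, 0.04) * geometry$center_span_az
    az <- pmin(pmax(az, -geometry$center_span_az / 2),
               geometry$center_span_az / 2)
  }
  el <- runif(n_templates, -geometry$center_span_el / 2,
              geometry$center_span_el / 2)
  rfs <- data.frame(neuron_id = seq_len(n_templates), center_az = az,
                    center_el = el, diameter = geometry$diameter,
                    polarity = geometry$polarity,
                    stringsAsFactors = FALSE)
  class(rfs) <- c("receptive_fields", "data.frame")
  attr(rfs, "geometry") <- geometry
  rfs
}

#' Pairwise receptive-field separations in RFCD units
#'
#' @param rfs a `receptive_fields` data.frame (templates or population
#'   members with columns `center_az`, `center_el`, `diameter`).
#' @return numeric vector of centre distances divided by the larger of the
#'   two centre diameters, one per unordered pair.
#' @export
pairwise_separations <- function(rfs) {
  n <- nrow(rfs)
  if (n < 2) return(numeric(0))
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  d <- sqrt((rfs$center_az[idx[, 1]] - rfs$center_az[idx[, 2]])^2 +
            (rfs$center_el[idx[, 1]] - rfs$center_el[idx[, 2]])^2)
  d / pmax(rfs$diameter[idx[, 1]], rfs$diameter[idx[, 2]])
}

#' Response latency of a receptive-field position under a drifting grating
#'
#' A neuron whose RF centre lies further along the drift direction is excited
#' later; the offset is the centre position projected on the drift axis,
#' converted to time by the ratio of spatial to temporal frequency.
#'
#' @param center_az,center_el RF centre (deg).
#' @param stim a [grating_stimulus()].
#' @return latency in seconds (signed, not wrapped).
#' @keywords internal
position_latency <- function(center_az, center_el, stim) {
  u <- drift_unit(stim$direction_deg)
  (center_az * u[1] + center_el * u[2]) * stim$spatial_freq /
    stim$temporal_freq
}

#' Simulate template LGN responses to a drifting grating
#'
#' Event-based generator: each grating cycle evokes one response event whose
#' phase is fixed by the neuron's RF centre projected on the drift axis. The
#' spike count per event is Poisson with mean `rate_mean * period`, so the
#' grand mean rate equals `rate_mean` and is independent of direction (phase
#' shifts only). Event spikes are Gaussian-jittered (SD `event_timescale`);
#' tail spikes decay exponentially (`tail_tau`). An event-based process
#' rather than a rate-modulated Poisson process is used because the jitter
#' analysis downstream requires identifiable response events whose timing SD
#' can be controlled without confounding count noise with timing noise.
#'
#' @param rfs templates from [make_template_population()].
#' @param stim a [grating_stimulus()] (one direction).
#' @param psth a [cycle_psth()].
#' @param n_trials trials to simulate (>= 1).
#' @param rng_seed integer seed.
#' @return data.frame of class `spike_trains` with columns `neuron_id`,
#'   `direction_deg`, `trial`, `time_s`; times sorted within each
#'   (neuron, trial) and contained in \[0, duration\].
#' @export
simulate_lgn_responses <- function(rfs, stim, psth, n_trials, rng_seed = 1) {
  stopifnot(n_trials >= 1)
  if (stim$duration <= 0) stop("zero-duration stimulus")
  if (psth$event_timescale < 0) stop("negative event timescale")
  set.seed(rng_seed)
  period <- stim$period
  n_cycles <- max(1L, floor(stim$duration / period))
  mean_per_event <- psth$rate_mean * stim$duration / n_cycles
  # per-trial session gain, shared across the simultaneously recorded
  # neurons (slow excitability fluctuations under anesthesia)
  cv <- psth$trial_gain_cv
  gains <- if (cv > 0) rgamma(n_trials, shape = 1 / cv^2, rate = 1 / cv^2)
           else rep(1, n_trials)
  out <- vector("list", nrow(rfs) * n_trials)
  k <- 0L
  for (i in seq_len(nrow(rfs))) {
    lat <- position_latency(rfs$center_az[i], rfs$center_el[i], stim)
    event_times <- (seq_len(n_cycles) - 1 + psth$event_phase) * period + lat
    for (tr in seq_len(n_trials)) {
      counts <- stats::rpois(n_cycles, gains[tr] * mean_per_event)
      n_sp <- sum(counts)
      if (n_sp == 0) next
      ev <- rep(event_times, counts)
      is_tail <- runif(n_sp) < psth$tail_fraction
      dt <- numeric(n_sp)
      dt[!is_tail] <- rnorm(sum(!is_tail), 0, psth$event_timescale)
      dt[is_tail] <- rexp(sum(is_tail), 1 / psth$tail_tau)
      t_sp <- wrap_times(ev + dt, period, stim$duration)
      k <- k + 1L
      out[[k]] <- data.frame(neuron_id = rfs$neuron_id[i],
                             direction_deg = stim$direction_deg,
                             trial = tr, time_s = sort(t_sp))
    }
  }
  res <- do.call(rbind, out[seq_len(k)])
  if (is.null(res))
    res <- data.frame(neuron_id = integer(0), direction_deg = numeric(0),
                      trial = integer(0), time_s = numeric(0))
  class(res) <- c("spike_trains", "data.frame")
  res
}

#' Simulate template responses over a set of directions
#'
#' @inheritParams simulate_lgn_responses
#' @param directions vector of drift directions (deg).
#' @param stim_base a [grating_stimulus()] whose direction is overridden.
#' @return `spike_trains` data.frame covering all directions.
#' @export
simulate_lgn_directions <- function(rfs, directions, psth, n_trials,
                                    stim_base = grating_stimulus(),
                                    rng_seed = 1) {
  res <- lapply(seq_along(directions), function(j) {
    stim <- stim_base
    stim$direction_deg <- directions[j] %% 360
    simulate_lgn_responses(rfs, stim, psth, n_trials,
                           rng_seed = derive_seed(rng_seed,
                                                  paste0("dir", directions[j])))
  })
  out <- do.call(rbind, res)
  class(out) <- c("spike_trains", "data.frame")
  out
}
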