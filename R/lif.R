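# Leaky integrate-and-fire model of the layer 4 cortical neuron driven by the
# pooled LGN population spike train through identical exponential EPSCs.

#' Integrate-and-fire and EPSC constants
#'
#' Membrane equation: `tau_m * dV/dt = -(V - e_rest) + r_m * I_syn`,
#' integrated by forward Euler at step `dt`. When V crosses `v_thresh` a
#' spike is recorded, V is set to `v_spike` for exactly one sample (the
#' cosmetic spike of the hard-reset model), then clamped at `v_reset` for
#' the refractory period.
#'
#' `v_thresh` and `r_m` are not experimentally constrained here; the model
#' is robust to threshold/reset changes and sensitive only to EPSC efficacy,
#' and the defaults place the cell in the sufficient-firing regime (a volley
#' of roughly half a dozen near-coincident EPSCs reaches threshold) — see
#' the methods vignette.
#'
#' @param e_rest resting potential (mV).
#' @param v_thresh spike threshold (mV).
#' @param v_spike potential at the spike sample (mV).
#' @param v_reset reset potential held during refractoriness (mV).
#' @param tau_m membrane time constant (ms).
#' @param r_m membrane resistance (MOhm).
#' @param t_refract refractory period (ms).
#' @param dt Euler step (ms); must be below `tau_m` and `tau_epsc`.
#' @param i0 EPSC amplitude (nA); effective range 0.05-0.1.
#' @param tau_epsc EPSC decay time constant (ms); effective range 2-5.
#' @return object of class `lif_config`.
#' @export
lif_config <- function(e_rest = -70, v_thresh = -55, v_spike = 0,
                       v_reset = -65, tau_m = 2, r_m = 52, t_refract = 3,
                       dt = 0.05, i0 = 0.055, tau_epsc = 4) {
  stopifnot(v_reset < v_thresh, v_thresh < v_spike, dt > 0, dt < tau_m,
            dt < tau_epsc, t_refract >= 0, tau_m > 0, r_m > 0, i0 > 0,
            tau_epsc > 0)
  structure(list(e_rest = e_rest, v_thresh = v_thresh, v_spike = v_spike,
                 v_reset = v_reset, tau_m = tau_m, r_m = r_m,
                 t_refract = t_refract, dt = dt, i0 = i0,
                 tau_epsc = tau_epsc),
            class = "lif_config")
}

#' Summed exponential EPSC current from pooled input spikes
#'
#' Each input spike lays down `i0 * exp(-(t - t_k)/tau_epsc)` for t >= t_k
#' (amplitude `i0` at the spike's own sample, inclusive); currents sum
#' linearly across all inputs and are sampled on the `dt` grid.
#'
#' @param spike_times pooled input spike times (s), within \[0, duration\].
#' @param cfg a [lif_config()].
#' @param duration trial duration (s).
#' @return object of class `syn_current`: `time_s`, `i_syn_na`, `dt_ms`.
#' @export
synaptic_current <- function(spike_times, cfg, duration) {
  cur <- epsc_current_cpp(as.numeric(spike_times), duration, cfg$dt,
                          cfg$i0, cfg$tau_epsc)
  structure(list(time_s = seq(0, by = cfg$dt / 1000,
                              length.out = length(cur)),
                 i_syn_na = cur, dt_ms = cfg$dt),
            class = "syn_current")
}

#' Forward-Euler integration of the membrane equation
#'
#' @param i_syn a [synaptic_current()] result or a plain numeric current
#'   vector sampled at `cfg$dt`.
#' @param cfg a [lif_config()].
#' @param return_trace keep the full membrane trace (set FALSE in sweeps).
#' @return object of class `membrane_trace`: `time_s`, `v_mv` (if traced),
#'   `i_syn_na`, `spike_times_s`, `n_spikes`, `cfg`.
#' @export
integrate_lif <- function(i_syn, cfg, return_trace = TRUE) {
  cur <- if (inherits(i_syn, "syn_current")) i_syn$i_syn_na
         else as.numeric(i_syn)
  res <- lif_integrate_cpp(cur, cfg$dt, cfg$e_rest, cfg$v_thresh,
                           cfg$v_spike, cfg$v_reset, cfg$tau_m, cfg$r_m,
                           cfg$t_refract, return_trace)
  if (any(!is.finite(res$spike_times)) ||
      (return_trace && any(!is.finite(res$v))))
    stop("numerical overflow in LIF integration")
  structure(list(time_s = seq(0, by = cfg$dt / 1000, length.out = length(cur)),
                 v_mv = if (return_trace) res$v else NULL,
                 i_syn_na = cur, spike_times_s = res$spike_times,
                 n_spikes = res$n_spikes, cfg = cfg),
            class = "membrane_trace")
}

#' Cortical response to a pooled input spike train
#'
#' Fused EPSC-superposition + Euler path used by the simulation sweeps.
#'
#' @inheritParams synaptic_current
#' @param return_trace keep membrane and current traces.
#' @return as [integrate_lif()].
#' @export
lif_response <- function(spike_times, cfg, duration, return_trace = FALSE) {
  res <- lif_from_spikes_cpp(as.numeric(spike_times), duration, cfg$dt,
                             cfg$e_rest, cfg$v_thresh, cfg$v_spike,
                             cfg$v_reset, cfg$tau_m, cfg$r_m, cfg$t_refract,
                             cfg$i0, cfg$tau_epsc, return_trace)
  structure(list(time_s = if (return_trace)
                   seq(0, by = cfg$dt / 1000, length.out = length(res$v))
                 else NULL,
                 v_mv = if (return_trace) res$v else NULL,
                 i_syn_na = if (return_trace) res$i_syn else NULL,
                 spike_times_s = res$spike_times, n_spikes = res$n_spikes,
                 cfg = cfg),
            class = "membrane_trace")
}

#' Simulate one stimulus condition: per-trial cortical spike counts
#'
#' For each trial a fresh controlled-jitter population input is generated,
#' pooled, and integrated through the LIF model. The default input
#' construction (`input = "resampled"`) draws a fresh random 0-degree trial
#' of the appropriate template for every member on every simulation trial
#' ([controlled_population_input()]); `input = "donor"` replays one fixed
#' donor trial for all members ([apply_controlled_jitter()]), which removes
#' input spike-count variability and is used by the calibration oracles.
#'
#' @param layout a [fill_population()] result.
#' @param template_trial donor spike-time vector (s); required for
#'   `input = "donor"`.
#' @param profile a [jitter_profile()].
#' @param direction_deg drift direction (deg).
#' @param n_trials trials to simulate.
#' @param cfg a [lif_config()].
#' @param stim a [grating_stimulus()].
#' @param rng_seed integer seed.
#' @param donor_template donor template id (`input = "donor"`).
#' @param keep_spike_times also return per-trial cortical spike times.
#' @param mean_trace accumulate the trial-averaged membrane potential.
#' @param input input construction: "resampled" (default) or "donor".
#' @param bank a [template_trial_bank()]; required for
#'   `input = "resampled"`.
#' @return list of class `condition_result`: `counts` (data.frame
#'   direction_deg, sigma_min_s, trial, spike_count), optional
#'   `spike_times` (list), optional `mean_v` (mV on the dt grid).
#' @export
run_condition <- function(layout, template_trial = NULL, profile,
                          direction_deg, n_trials, cfg = lif_config(),
                          stim = grating_stimulus(), rng_seed = 1,
                          donor_template = 1, keep_spike_times = FALSE,
                          mean_trace = FALSE,
                          input = c("resampled", "donor"), bank = NULL) {
  input <- match.arg(input)
  if (input == "resampled" && is.null(bank))
    stop("input = \"resampled\" needs a template_trial_bank()")
  if (input == "donor" && is.null(template_trial))
    stop("input = \"donor\" needs a donor template_trial")
  counts <- integer(n_trials)
  st <- if (keep_spike_times) vector("list", n_trials) else NULL
  vsum <- NULL
  for (tr in seq_len(n_trials)) {
    seed_tr <- derive_seed(rng_seed, paste0("trial", tr))
    if (input == "resampled") {
      pooled <- controlled_population_input(layout, bank, profile,
                                            direction_deg, stim,
                                            rng_seed = seed_tr)
    } else {
      pop <- apply_controlled_jitter(template_trial, layout, profile,
                                     direction_deg, stim,
                                     rng_seed = seed_tr,
                                     donor_template = donor_template)
      pooled <- sort(pop$time_s)
    }
    resp <- lif_response(pooled, cfg, stim$duration,
                         return_trace = mean_trace)
    counts[tr] <- resp$n_spikes
    if (keep_spike_times) st[[tr]] <- resp$spike_times_s
    if (mean_trace) {
      if (is.null(vsum)) vsum <- resp$v_mv else vsum <- vsum + resp$v_mv
    }
  }
  structure(list(counts = data.frame(direction_deg = direction_deg,
                                     sigma_min_s = profile$sigma_min,
                                     trial = seq_len(n_trials),
                                     spike_count = counts),
                 spike_times = st,
                 mean_v = if (mean_trace) vsum / n_trials else NULL),
            class = "condition_result")
}

#' Classify the cortical firing regime
#'
#' The model's sensitivity to EPSC efficacy manifests as one of three
#' states: impoverished, sufficient, or strong cortical firing. The
#' classifier thresholds the mean spike count per trial at the preferred
#' orientation.
#'
#' @param peak_mean_count mean spike count per trial at the preferred
#'   orientation.
#' @param thresholds length-2: below the first is impoverished, above the
#'   second is strong.
#' @return one of "impoverished", "sufficient", "strong".
#' @export
classify_firing_regime <- function(peak_mean_count, thresholds = c(2, 60)) {
  if (peak_mean_count < thresholds[1]) "impoverished"
  else if (peak_mean_count > thresholds[2]) "strong"
  else "sufficient"
}
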