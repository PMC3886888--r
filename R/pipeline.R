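# End-to-end orchestration: a declarative run configuration drives
# generate -> fill -> jitter -> simulate -> analyze with deterministic
# seeding, and writes all intermediate tables plus a summary and manifest.

#' Default sigma_min sweep (seconds)
#'
#' Eight levels spanning the 6-40 ms range of population timing jitter.
#' @export
default_sigma_sweep <- function() c(6, 10, 14, 18, 22, 26, 33, 40) / 1000

#' Build a run configuration
#'
#' A nested list covering every stage: stimulus grid, generator, population,
#' jitter profile and sweep, LIF constants, and analysis settings. Every
#' stochastic stage derives its seed deterministically from the master
#' `seed` and the stage name, so one integer reproduces the experiment. The
#' configuration round-trips losslessly through YAML
#' ([write_run_config()] / [read_run_config()]).
#'
#' @param seed master integer seed.
#' @param ... named overrides of the default blocks (partial lists are
#'   merged recursively).
#' @return object of class `run_config`.
#' @export
run_config <- function(seed = 1, ...) {
  base <- list(
    seed = seed,
    stimulus = list(directions = seq(0, 315, by = 45), spatial_freq = 0.5,
                    temporal_freq = 5, contrast = 1, duration = 1),
    generator = list(n_templates = 5, n_trials = 30,
                     psth = list(event_phase = 0.25, event_timescale = 0.013,
                                 rate_mean = 22, tail_fraction = 0.3,
                                 tail_tau = 0.040, trial_gain_cv = 0.6),
                     geometry = list(center_span_az = 1.6,
                                     center_span_el = 0.45,
                                     diameter = 1.0)),
    population = list(target_size = 30,
                      separation = list(support = c(0.4, 2.0), mode = 1.0,
                                        sd = 0.4),
                      overlap_tol = 0.8, boundary = "wrap"),
    jitter = list(sigma_min_sweep = default_sigma_sweep(),
                  sigma_max = 0.100, width_deg = 25, theta_pref = 90,
                  n_refills = 100),
    lif = list(e_rest = -70, v_thresh = -55, v_spike = 0, v_reset = -65,
               tau_m = 2, r_m = 52, t_refract = 3, dt = 0.05, i0 = 0.055,
               tau_epsc = 4),
    analysis = list(tuning_step_deg = 5, n_trials = 100, grid_step = 1,
                    width_scales = c(0.25, 1, 2), width_trials = 60,
                    width_sigma_sweep = c(6, 12, 18, 25, 33, 40) / 1000))
  cfg <- modifyList(base, list(...))
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = "run_config")
}

#' Reduced-scale profiles
#'
#' `smoke_config` finishes in about a minute (plumbing checks); `desk_config`
#' is the reduced working scale of the full experiment (5-degree tuning
#' grid, 100 trials, 8 jitter levels); `paper_config` is the full-resolution
#' profile (1-degree grid, 250 trials) and is long-running.
#'
#' @param seed master seed.
#' @return a [run_config()].
#' @export
smoke_config <- function(seed = 1) {
  run_config(seed,
             generator = list(n_trials = 8),
             jitter = list(sigma_min_sweep = c(6, 16, 28, 40) / 1000,
                           n_refills = 5),
             analysis = list(tuning_step_deg = 15, n_trials = 25,
                             width_scales = numeric(0)))
}

#' @rdname smoke_config
#' @export
desk_config <- function(seed = 1) run_config(seed)

#' @rdname smoke_config
#' @export
paper_config <- function(seed = 1) {
  run_config(seed,
             analysis = list(tuning_step_deg = 1, n_trials = 250))
}

#' Write / read a run configuration as YAML
#'
#' @param config a [run_config()].
#' @param path file path.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(run_config, c(list(seed = cfg$seed),
                        cfg[setdiff(names(cfg), "seed")]))
}

config_hash <- function(config) {
  s <- yaml::as.yaml(unclass(config))
  m <- 2147483647
  h <- 7
  for (k in utf8ToInt(s)) h <- (h * 131 + k) %% m
  sprintf("%08x", h)
}

# -- stage helpers shared by run_experiment, the analysis scripts, and the
#    acceptance measurements ------------------------------------------------

cfg_stim <- function(config, direction = 0) {
  s <- config$stimulus
  grating_stimulus(direction, s$spatial_freq, s$temporal_freq, s$contrast,
                   s$duration)
}

cfg_psth <- function(config) do.call(cycle_psth, config$generator$psth)

cfg_geometry <- function(config) do.call(template_geometry,
                                         config$generator$geometry)

cfg_sep_model <- function(config) {
  p <- config$population$separation
  separation_model(support = p$support, mode = p$mode, sd = p$sd)
}

cfg_lif <- function(config) do.call(lif_config, config$lif)

cfg_profile <- function(config, sigma_min) {
  j <- config$jitter
  jitter_profile(sigma_min, j$sigma_max, j$width_deg, j$theta_pref)
}

#' Generate the template world of a configuration
#'
#' Templates, their multi-trial responses over the configured direction
#' grid, one population fill, and the donor trial (first 0-degree trial of
#' the first template) used by the controlled-jitter stages.
#'
#' @param config a [run_config()].
#' @return list: `templates`, `trains`, `layout`, `donor_trial`, `bank`
#'   (a [template_trial_bank()]), `psth`.
#' @export
build_world <- function(config) {
  templates <- make_template_population(config$generator$n_templates,
                                        cfg_geometry(config),
                                        rng_seed = derive_seed(config$seed,
                                                               "templates"))
  psth <- cfg_psth(config)
  dirs <- unique(c(config$stimulus$directions, 0))
  trains <- simulate_lgn_directions(templates, dirs, psth,
                                    config$generator$n_trials,
                                    cfg_stim(config),
                                    rng_seed = derive_seed(config$seed,
                                                           "trains"))
  layout <- fill_population(templates, cfg_sep_model(config),
                            config$population$target_size,
                            rng_seed = derive_seed(config$seed, "fill"),
                            overlap_tol = config$population$overlap_tol)
  donor <- trains$time_s[trains$neuron_id == 1 & trains$direction_deg == 0 &
                           trains$trial == 1]
  bank <- template_trial_bank(trains, templates, cfg_stim(config))
  list(templates = templates, trains = trains, layout = layout,
       donor_trial = donor, bank = bank, psth = psth)
}

#' Simulate the cortical tuning sweep over jitter levels
#'
#' @param world a [build_world()] result.
#' @param config a [run_config()].
#' @param sigma_levels jitter floors (s); defaults to the configured sweep.
#' @param directions tuning directions (deg); defaults to the configured
#'   180-degree span around the preferred direction.
#' @param n_trials trials per condition.
#' @return data.frame `sigma_min_s`, `direction_deg`, `trial`,
#'   `spike_count`.
#' @export
run_tuning_sweep <- function(world, config,
                             sigma_levels = config$jitter$sigma_min_sweep,
                             directions = NULL,
                             n_trials = config$analysis$n_trials) {
  if (is.null(directions)) {
    step <- config$analysis$tuning_step_deg
    directions <- seq(0, 180 - step, by = step)
  }
  cfg <- cfg_lif(config)
  stim <- cfg_stim(config)
  out <- vector("list", length(sigma_levels) * length(directions))
  k <- 0L
  for (sg in sigma_levels) {
    prof <- cfg_profile(config, sg)
    for (th in directions) {
      k <- k + 1L
      res <- run_condition(world$layout, world$donor_trial, prof, th,
                           n_trials, cfg, stim,
                           rng_seed = derive_seed(config$seed,
                                                  paste0("sim", sg, "_", th)),
                           bank = world$bank)
      out[[k]] <- res$counts
    }
  }
  do.call(rbind, out)
}

#' Simulate the tuning-width sweep
#'
#' Tuning width is modulated by scaling the jitter-profile dip width; for
#' each width scale the full sigma_min sweep is simulated.
#'
#' @param world a [build_world()] result.
#' @param config a [run_config()].
#' @param width_scales multipliers on the calibrated profile width.
#' @param sigma_levels jitter floors (s).
#' @param n_trials trials per condition.
#' @param directions tuning directions (deg).
#' @return data.frame with `width_scale` plus the [run_tuning_sweep()]
#'   columns.
#' @export
run_width_sweep_sim <- function(world, config,
                                width_scales = config$analysis$width_scales,
                                sigma_levels =
                                  config$analysis$width_sigma_sweep,
                                n_trials = config$analysis$width_trials,
                                directions = NULL) {
  out <- vector("list", length(width_scales))
  for (i in seq_along(width_scales)) {
    cfg_i <- config
    cfg_i$jitter$width_deg <- config$jitter$width_deg * width_scales[i]
    counts <- run_tuning_sweep(world, cfg_i, sigma_levels = sigma_levels,
                               directions = directions, n_trials = n_trials)
    counts$width_scale <- width_scales[i]
    out[[i]] <- counts
  }
  do.call(rbind, out)
}

#' Run the full experiment from a configuration
#'
#' Stages: generate templates and responses, fill the population, measure
#' the multi-trial jitter tuning curve, simulate the cortical sweep over
#' jitter levels, and analyse tuning, mean-variance and information
#' efficiency. All intermediate tables, summary scalars (JSON) and a
#' manifest (config hash, seed, versions) are written under `out_dir`.
#'
#' @param config a [run_config()].
#' @param out_dir output directory (created if missing).
#' @param width_sweep also run the tuning-width sweep block.
#' @return list with the in-memory results (`world`, `jitter`, `counts`,
#'   `tuning`, `mean_variance`, `efficiency`, `summary`), invisibly.
#' @export
run_experiment <- function(config, out_dir, width_sweep = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  t0 <- Sys.time()
  log_stage <- function(name, t_start)
    message(sprintf("[%s] done in %.1f s", name,
                    as.numeric(difftime(Sys.time(), t_start,
                                        units = "secs"))))

  ts <- Sys.time()
  world <- build_world(config)
  write_rf_table(world$templates, file.path(out_dir, "templates.tsv"))
  write_rf_table(world$layout$members, file.path(out_dir, "population.tsv"))
  write_spike_table(world$trains, file.path(out_dir, "template_spikes.tsv"))
  write_layout_provenance(world$layout, file.path(out_dir, "provenance.tsv"))
  log_stage("generate+fill", ts)

  ts <- Sys.time()
  jit <- jitter_tuning_curve(world$templates, world$trains,
                             config$stimulus$directions,
                             cfg_stim(config), cfg_sep_model(config),
                             config$population$target_size,
                             n_refills = config$jitter$n_refills,
                             rng_seed = derive_seed(config$seed, "jitter"))
  write.table(jit$curve, file.path(out_dir, "jitter_curve.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  log_stage("jitter", ts)

  ts <- Sys.time()
  counts <- run_tuning_sweep(world, config)
  write.table(counts, file.path(out_dir, "cortical_counts.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  log_stage("simulate", ts)

  ts <- Sys.time()
  low <- min(counts$sigma_min_s)
  tun <- fit_tuning(counts[counts$sigma_min_s == low, ])
  mv <- mean_variance_relation(counts[counts$sigma_min_s > 0.010, ])
  eff <- efficiency_analysis(counts, grid_step = config$analysis$grid_step)
  ws <- NULL
  if (width_sweep && length(config$analysis$width_scales) > 0) {
    wcounts <- run_width_sweep_sim(world, config)
    write.table(wcounts, file.path(out_dir, "width_sweep_counts.tsv"),
                sep = "\t", row.names = FALSE, quote = FALSE)
    ws <- width_sweep(wcounts)
  }
  write.table(eff$by_level, file.path(out_dir, "efficiency.tsv"),
              sep = "\t", row.names = FALSE, quote = FALSE)
  log_stage("analyze", ts)

  summary <- list(
    jitter_floor_ms = 1000 *
      min(jit$curve$delta_t_s[jit$curve$direction_deg %in%
                                c(jit$theta_pref, jit$theta_pref + 180)]),
    jitter_ceiling_ms = 1000 * max(jit$curve$delta_t_s),
    jitter_dip_width_deg = if (!is.null(jit$dip)) jit$dip$width_deg else NA,
    hwhh_low_jitter_deg = tun$hwhh_deg,
    mean_variance_slope = mv$slope,
    ips_vertex_ms = eff$vertex_ms,
    ips_argmax_ms = eff$argmax_ms)
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  manifest <- list(config_hash = config_hash(config), seed = config$seed,
                   r_version = R.version.string,
                   package_version =
                     as.character(utils::packageVersion("thalsync")),
                   elapsed_s = as.numeric(difftime(Sys.time(), t0,
                                                   units = "secs")))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  write_run_config(config, file.path(out_dir, "config.yaml"))
  invisible(list(world = world, jitter = jit, counts = counts, tuning = tun,
                 mean_variance = mv, efficiency = eff, width_sweep = ws,
                 summary = summary))
}
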