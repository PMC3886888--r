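# Population filling: expand recorded/synthetic templates into the ~30-neuron
# convergent LGN population by receptive-field duplication and translation
# under the measured separation distribution, and convert spatial shifts into
# stimulus-dependent response-latency shifts.

#' Receptive-field separation model
#'
#' Probability density of pairwise RF separations (in RFCD units) for LGN
#' neurons converging on a common cortical target, supported on \[0.4, 2.0\].
#' The default is a truncated Gaussian with mode 1.0 and SD 0.4 normalised on
#' the support, approximating the unimodal experimentally measured curve. A
#' tabulated density can be supplied instead so the model is replaceable
#' without code changes.
#'
#' @param support separation interval (RFCD units).
#' @param mode,sd location and scale of the default truncated Gaussian.
#' @param density_table optional data.frame with columns `x`, `density`
#'   overriding the parametric form (renormalised on `support`).
#' @return object of class `separation_model` with `density(x)` and a
#'   precomputed inverse-CDF sampler.
#' @export
separation_model <- function(support = c(0.4, 2.0), mode = 1.0, sd = 0.4,
                             density_table = NULL) {
  stopifnot(length(support) == 2, support[1] > 0, support[2] > support[1])
  grid <- seq(support[1], support[2], length.out = 801)
  if (is.null(density_table)) {
    dens <- exp(-(grid - mode)^2 / (2 * sd^2))
  } else {
    stopifnot(all(c("x", "density") %in% names(density_table)))
    dens <- approx(density_table$x, density_table$density, xout = grid,
                   rule = 2)$y
    if (any(dens < 0)) stop("separation density must be non-negative")
  }
  dx <- diff(grid[1:2])
  z <- sum(dens) * dx
  dens <- dens / z
  cdf <- cumsum(dens) * dx
  cdf <- cdf / cdf[length(cdf)]
  structure(list(support = support, grid = grid, dens = dens, cdf = cdf,
                 density = function(x) {
                   y <- approx(grid, dens, xout = x, rule = 1)$y
                   y[is.na(y)] <- 0
                   y
                 },
                 sample = function(n) {
                   approx(cdf, grid, xout = runif(n), rule = 2)$y
                 }),
            class = "separation_model")
}

#' Fill a template cluster out to a full convergent population
#'
#' Duplicates templates and translates their RF centres so that (a) every
#' shifted centre stays inside the bounding region of the original template
#' cluster (the visual space covered does not change) and (b) member-to-anchor
#' separations follow the separation model. Each new member copies a randomly
#' chosen template, and its centre is placed at a distance drawn from
#' `sep_model` (scaled by the larger centre diameter) from a randomly chosen
#' already-placed member, in a uniformly random direction; proposals outside
#' the region or closer than the minimum allowed distance to any existing
#' member are rejected and redrawn.
#'
#' The hard support bounds cannot hold for every pair of a 30-member
#' population (a circle-packing impossibility; see the methods vignette), so
#' the lower bound is enforced as a soft minimum pairwise distance
#' `0.4 * (1 - overlap_tol)` RFCD, while the upper bound 2.0 holds for all
#' pairs whenever the template region diagonal is below 2.0 RFCD (true for
#' the default geometry).
#'
#' @param templates templates from [make_template_population()].
#' @param sep_model a [separation_model()].
#' @param target_size population size (default 30; must be >= templates).
#' @param rng_seed integer seed.
#' @param overlap_tol fraction by which the 0.4-RFCD lower support bound may
#'   be violated between non-anchored pairs (default 0.8).
#' @param max_proposals rejection-sampling budget per member.
#' @param max_restarts whole-fill restarts before failing with a diagnostic.
#' @param region optional override of the bounding region,
#'   `list(az = c(lo, hi), el = c(lo, hi))` in degrees.
#' @return object of class `population_layout`: list with `members` (a
#'   `receptive_fields` data.frame with `template_id`, `shift_az`,
#'   `shift_el`, `anchored_sep` columns), `templates`, `region`, and
#'   `theta_pref` (synchrony-preferred drift direction, degrees).
#' @export
fill_population <- function(templates, sep_model = separation_model(),
                            target_size = 30, rng_seed = 1,
                            overlap_tol = 0.8, max_proposals = 10000,
                            max_restarts = 50, region = NULL) {
  n_t <- nrow(templates)
  stopifnot(n_t >= 1, target_size >= n_t)
  if (is.null(region)) {
    # the nominal cluster region of the template geometry when known (the
    # realized template centres sample it sparsely), else their bounding box
    geo <- attr(templates, "geometry")
    if (!is.null(geo)) {
      region <- list(az = c(-1, 1) * geo$center_span_az / 2,
                     el = c(-1, 1) * geo$center_span_el / 2)
    } else {
      region <- list(az = range(templates$center_az),
                     el = range(templates$center_el))
    }
  }
  set.seed(rng_seed)
  min_sep <- 0.4 * (1 - overlap_tol)
  batch <- 200L

  fill_once <- function() {
    az <- templates$center_az
    el <- templates$center_el
    dia <- templates$diameter
    tid <- templates$neuron_id
    asep <- rep(NA_real_, n_t)
    for (m in seq_len(target_size - n_t)) {
      placed <- FALSE
      for (p in seq_len(ceiling(max_proposals / batch))) {
        a <- sample.int(length(az), batch, replace = TRUE)
        tpl <- sample.int(n_t, batch, replace = TRUE)
        s <- sep_model$sample(batch)
        ang <- runif(batch, 0, 2 * pi)
        d_ref <- pmax(dia[a], templates$diameter[tpl])
        cand_az <- az[a] + s * d_ref * cos(ang)
        cand_el <- el[a] + s * d_ref * sin(ang)
        ok <- cand_az >= region$az[1] & cand_az <= region$az[2] &
          cand_el >= region$el[1] & cand_el <= region$el[2]
        for (q in which(ok)) {
          dd <- sqrt((az - cand_az[q])^2 + (el - cand_el[q])^2) /
            pmax(dia, templates$diameter[tpl[q]])
          if (all(dd >= min_sep)) {
            az <- c(az, cand_az[q]); el <- c(el, cand_el[q])
            dia <- c(dia, templates$diameter[tpl[q]])
            tid <- c(tid, tpl[q])
            asep <- c(asep, s[q])
            placed <- TRUE
            break
          }
        }
        if (placed) break
      }
      if (!placed) return(NULL)
    }
    list(az = az, el = el, dia = dia, tid = tid, asep = asep)
  }

  res <- NULL
  for (r in seq_len(max_restarts)) {
    res <- fill_once()
    if (!is.null(res)) break
  }
  if (is.null(res))
    stop("population fill failed: could not place ", target_size - n_t,
         " members in region [", paste(round(unlist(region), 2),
                                       collapse = ", "),
         "] with min separation ", round(min_sep, 3), " RFCD after ",
         max_restarts, " restarts of ", max_proposals, " proposals each")

  members <- data.frame(
    member_id = seq_len(target_size),
    template_id = res$tid,
    center_az = res$az, center_el = res$el, diameter = res$dia,
    polarity = templates$polarity[1],
    shift_az = res$az - templates$center_az[res$tid],
    shift_el = res$el - templates$center_el[res$tid],
    anchored_sep = res$asep, stringsAsFactors = FALSE)
  class(members) <- c("receptive_fields", "data.frame")
  # synchrony-preferred drift: perpendicular to the cluster's major axis, so
  # that latency spread along the drift axis is minimal
  theta_pref <- if (diff(region$az) >= diff(region$el)) 90 else 0
  structure(list(members = members, templates = templates, region = region,
                 theta_pref = theta_pref, overlap_tol = overlap_tol),
            class = "population_layout")
}

#' Shift latency between two receptive fields under a drifting grating
#'
#' The timing offset between peak excitation at two RF centres equals
#' `d * cos(phi) * f_s / f_t`, where `d` is the centre separation, `phi` the
#' angle between the inter-centre axis and the drift direction (perpendicular
#' to the grating edge), and `f_s`, `f_t` the spatial and temporal
#' frequencies. The sign says which field is excited first (positive when
#' `rf_b` lies further along the drift direction, hence is excited later).
#' Latencies are not wrapped and may exceed one stimulus period.
#'
#' @param rf_a,rf_b single-row `receptive_fields` entries (or lists with
#'   `center_az`, `center_el`).
#' @param stim a [grating_stimulus()].
#' @return latency in seconds, signed.
#' @export
shift_latency <- function(rf_a, rf_b, stim) {
  position_latency(rf_b$center_az - rf_a$center_az,
                   rf_b$center_el - rf_a$center_el, stim)
}

#' Per-member latencies of a population layout
#'
#' @param layout a [fill_population()] result.
#' @param stim a [grating_stimulus()].
#' @param reference "template" gives each member's latency relative to its
#'   own template's centre (the shift latency added in multi-trial
#'   assembly); "absolute" gives latency relative to the visual-field origin
#'   (used when all members replay one donor trial).
#' @return numeric vector, seconds, one per member.
#' @export
member_latencies <- function(layout, stim,
                             reference = c("template", "absolute")) {
  reference <- match.arg(reference)
  m <- layout$members
  if (reference == "template")
    position_latency(m$shift_az, m$shift_el, stim)
  else
    position_latency(m$center_az, m$center_el, stim)
}

#' Assemble population spike trains from template recordings
#'
#' Each member is assigned a trial of its template and the member's shift
#' latency is added to all spike times in that trial. Spikes shifted past the
#' trial boundary are folded back by whole stimulus periods (the stimulus is
#' steady-state periodic, so folding preserves counts and phase); truncation
#' is available as an alternative boundary rule.
#'
#' @param layout a [fill_population()] result.
#' @param template_trains `spike_trains` for the template neurons containing
#'   the needed direction (multi-trial mode) or the 0-degree direction
#'   (single-trial-template mode).
#' @param stim a [grating_stimulus()] giving the direction being assembled.
#' @param mode "multi-trial": each member receives a random trial of its own
#'   template recorded at `stim$direction_deg`. "single-trial-template":
#'   each member receives a random trial of its template recorded at 0
#'   degrees (stimulus-driven timing then comes from the jitter profile).
#' @param rng_seed integer seed (trial assignment).
#' @param boundary "wrap" or "truncate".
#' @return `spike_trains` data.frame with members as `neuron_id`, plus an
#'   `assigned_trial` attribute recording the provenance
#'   (member, template, trial, latency).
#' @export
assemble_population_spikes <- function(layout, template_trains, stim,
                                       mode = c("multi-trial",
                                                "single-trial-template"),
                                       rng_seed = 1, boundary = "wrap") {
  mode <- match.arg(mode)
  set.seed(rng_seed)
  src_dir <- if (mode == "multi-trial") stim$direction_deg else 0
  src <- template_trains[template_trains$direction_deg == src_dir, ]
  if (nrow(src) == 0)
    stop("template trains contain no trials at direction ", src_dir)
  lat <- member_latencies(layout, stim, reference = "template")
  m <- layout$members
  prov <- data.frame(member_id = m$member_id, template_id = m$template_id,
                     trial = NA_integer_, latency_s = lat)
  out <- vector("list", nrow(m))
  for (i in seq_len(nrow(m))) {
    tpl <- src[src$neuron_id == m$template_id[i], ]
    trials <- unique(tpl$trial)
    if (length(trials) == 0)
      stop("no template trials for template ", m$template_id[i],
           " at direction ", src_dir)
    tr <- if (length(trials) == 1) trials else sample(trials, 1)
    prov$trial[i] <- tr
    t_sp <- tpl$time_s[tpl$trial == tr] + lat[i]
    t_sp <- wrap_times(t_sp, stim$period, stim$duration, boundary)
    out[[i]] <- data.frame(neuron_id = m$member_id[i],
                           direction_deg = stim$direction_deg,
                           trial = 1L, time_s = sort(t_sp))
  }
  res <- do.call(rbind, out)
  class(res) <- c("spike_trains", "data.frame")
  attr(res, "assigned_trial") <- prov
  res
}
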