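# Decoding analysis: orientation tuning curves and HWHH, spike-count
# mean-variance statistics, Poisson response models with Gaussian-smoothed
# rates, Fisher information, the Cramer-Rao estimator SD, and the
# information-per-spike efficiency metric.

#' Fit an orientation tuning curve
#'
#' Means and variances of the spike count per direction, with a local
#' Gaussian least-squares fit over a 180-degree span centred on the
#' empirical argmax of the mean count (drifting gratings are
#' direction-signed, so the two response lobes 180 degrees apart are
#' analysed separately). Tuning sharpness is the half-width at half-height,
#' `HWHH = fitted SD * sqrt(2 ln 2)`.
#'
#' @param counts data.frame with columns `direction_deg`, `spike_count`
#'   (one row per trial).
#' @return object of class `tuning_curve`: `stats` (data.frame
#'   direction_deg, offset_deg, lambda, var, n), `fit` (amp, center, sd,
#'   baseline), `theta_peak`, `hwhh_deg` (NA when flat), `flat` flag.
#' @export
fit_tuning <- function(counts) {
  ag <- stats::aggregate(spike_count ~ direction_deg, counts,
                         function(z) c(m = mean(z), v = var(z), n = length(z)))
  st <- data.frame(direction_deg = ag$direction_deg,
                   lambda = ag$spike_count[, "m"],
                   var = ag$spike_count[, "v"], n = ag$spike_count[, "n"])
  if (nrow(st) < 2) stop("need at least 2 distinct directions")
  theta_peak <- st$direction_deg[which.max(st$lambda)]
  off <- (st$direction_deg - theta_peak + 90) %% 180 - 90
  st$offset_deg <- off
  x <- st$offset_deg
  y <- st$lambda
  rng <- max(y) - min(y)
  flat <- FALSE
  fit_cf <- c(amp = 0, center = 0, sd = NA_real_, baseline = mean(y))
  if (rng > 1e-9) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ b + A * exp(-(x - cc)^2 / (2 * w^2)),
        start = list(A = rng, cc = 0, w = 15, b = min(y)),
        lower = c(A = 0, cc = -90, w = 1, b = 0),
        upper = c(A = Inf, cc = 90, w = 120, b = Inf)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      cf <- coef(fit)
      fit_cf <- c(amp = unname(cf["A"]), center = unname(cf["cc"]),
                  sd = unname(cf["w"]), baseline = unname(cf["b"]))
    } else flat <- TRUE
  } else flat <- TRUE
  # amplitude indistinguishable from noise -> flat tuning, HWHH undefined
  if (!flat && fit_cf["amp"] <= max(1e-8, 0.02 * max(y))) flat <- TRUE
  hwhh <- if (flat) NA_real_ else unname(fit_cf["sd"]) * sqrt(2 * log(2))
  structure(list(stats = st, fit = fit_cf, theta_peak = theta_peak,
                 hwhh_deg = hwhh, flat = flat),
            class = "tuning_curve")
}

#' Smoothed Poisson response model from a tuning curve
#'
#' Per-direction spike counts are modelled as Poisson with rate
#' `lambda_hat(theta)`, where `lambda_hat` is the Gaussian fit to the
#' empirical tuning curve evaluated on a fine grid (1 degree by default) —
#' smoothing is required because raw-rate fluctuations are magnified by
#' differentiation when computing Fisher information. Rates are floored at a
#' small positive value because the closed-form information divides by
#' `lambda_hat`.
#'
#' @param tuning a [fit_tuning()] result (must not be flat).
#' @param grid_step evaluation grid step (deg).
#' @param floor minimum rate (counts/trial).
#' @return object of class `response_model`: `theta_deg`, `offset_deg`,
#'   `lambda_hat`, `grid_step`.
#' @export
response_model <- function(tuning, grid_step = 1, floor = 1e-3) {
  if (tuning$flat)
    stop("flat tuning curve: response model undefined")
  cf <- tuning$fit
  off <- seq(-90, 90, by = grid_step)
  lam <- cf["baseline"] +
    cf["amp"] * exp(-(off - cf["center"])^2 / (2 * cf["sd"]^2))
  lam <- pmax(unname(lam), floor)
  structure(list(theta_deg = tuning$theta_peak + off, offset_deg = off,
                 lambda_hat = lam, grid_step = grid_step, floor = floor),
            class = "response_model")
}

#' Fisher information of a Poisson response model
#'
#' Computed two ways, both returned: (a) the expectation form
#' `J(theta) = E\[(d log p(n|theta) / d theta)^2\]` with the derivative taken
#' as a numerical central difference on the rate grid (forward/backward at
#' the edges) and terms with `p(n|theta) = 0` contributing zero; and (b) the
#' Poisson closed form `lambda'(theta)^2 / lambda(theta)` using the same
#' numerical derivative. The two agree on smooth inputs; the closed form is
#' exact for Poisson counts.
#'
#' @param model a [response_model()].
#' @param n_max highest spike count summed over in the expectation form
#'   (default covers the rate range to negligible tail mass).
#' @return data.frame of class `fisher_info`: `theta_deg`, `j_expectation`,
#'   `j_closed` (both in deg^-2).
#' @export
fisher_information <- function(model, n_max = NULL) {
  lam <- model$lambda_hat
  h <- model$grid_step
  k <- length(lam)
  if (is.null(n_max))
    n_max <- max(50, ceiling(qpois(1 - 1e-12, max(lam)) + 10))
  ns <- 0:n_max
  # numerical derivative of the rate (central; one-sided at grid edges)
  dl <- numeric(k)
  dl[2:(k - 1)] <- (lam[3:k] - lam[1:(k - 2)]) / (2 * h)
  dl[1] <- (lam[2] - lam[1]) / h
  dl[k] <- (lam[k] - lam[k - 1]) / h
  j_closed <- dl^2 / lam
  j_exp <- numeric(k)
  for (i in seq_len(k)) {
    im <- max(i - 1, 1)
    ip <- min(i + 1, k)
    denom <- (ip - im) * h
    p0 <- dpois(ns, lam[i])
    keep <- p0 > 0
    score <- (dpois(ns[keep], lam[ip], log = TRUE) -
              dpois(ns[keep], lam[im], log = TRUE)) / denom
    j_exp[i] <- sum(p0[keep] * score^2)
  }
  out <- data.frame(theta_deg = model$theta_deg, j_expectation = j_exp,
                    j_closed = j_closed)
  class(out) <- c("fisher_info", "data.frame")
  out
}

#' Spike-count mean-variance relation across orientations
#'
#' @param counts data.frame with `direction_deg`, `spike_count`, and
#'   optionally `sigma_min_s` (levels analysed separately and pooled).
#' @param through_origin fit the least-squares line with (FALSE, default) or
#'   without an intercept.
#' @return list of class `mean_variance`: `points` (per direction x level),
#'   `slope`, `intercept`, `slope_by_level`.
#' @export
mean_variance_relation <- function(counts, through_origin = FALSE) {
  if (is.null(counts$sigma_min_s)) counts$sigma_min_s <- -1
  pts <- do.call(rbind, lapply(split(counts, list(counts$sigma_min_s,
                                                  counts$direction_deg),
                                     drop = TRUE), function(d)
    data.frame(sigma_min_s = d$sigma_min_s[1],
               direction_deg = d$direction_deg[1],
               mean = mean(d$spike_count), var = var(d$spike_count))))
  if (nrow(pts) < 3) stop("need at least 3 (mean, variance) points")
  form <- if (through_origin) var ~ mean + 0 else var ~ mean
  fit <- lm(form, pts)
  slope_by_level <- do.call(rbind, lapply(split(pts, pts$sigma_min_s),
                                          function(d) {
    sl <- if (nrow(d) >= 3) unname(coef(lm(form, d))[["mean"]]) else NA_real_
    data.frame(sigma_min_s = d$sigma_min_s[1], slope = sl)
  }))
  structure(list(points = pts, slope = unname(coef(fit)[["mean"]]),
                 intercept = if (through_origin) 0
                             else unname(coef(fit)[[1]]),
                 slope_by_level = slope_by_level, fit = fit),
            class = "mean_variance")
}

#' Information-transmission efficiency over a minimum-jitter sweep
#'
#' For each `sigma_min` level: tuning fit, smoothed Poisson response model,
#' peak Fisher information `J_peak`, Cramer-Rao estimator SD
#' `1/sqrt(J_peak)`, peak mean spike count, and information per spike
#' `IPS = J_peak / peak count`. The IPS-versus-jitter curve is summarised by
#' a quadratic least-squares fit; its vertex is reported when interior to
#' the sweep, otherwise flagged as a boundary optimum.
#'
#' @param counts data.frame with `sigma_min_s`, `direction_deg`,
#'   `spike_count` over at least 4 jitter levels.
#' @param grid_step tuning evaluation grid (deg).
#' @return object of class `info_result`: `by_level` data.frame
#'   (sigma_min_ms, hwhh_deg, j_peak, est_sd_deg, peak_count, ips),
#'   `quad` coefficients, `vertex_ms`, `vertex_interior`, `argmax_ms`,
#'   `tunings` (list of fits).
#' @export
efficiency_analysis <- function(counts, grid_step = 1) {
  levels <- sort(unique(counts$sigma_min_s))
  if (length(levels) < 4) stop("need at least 4 sigma_min levels")
  rows <- vector("list", length(levels))
  tunings <- vector("list", length(levels))
  for (i in seq_along(levels)) {
    d <- counts[counts$sigma_min_s == levels[i], ]
    tun <- fit_tuning(d)
    tunings[[i]] <- tun
    if (tun$flat) {
      rows[[i]] <- data.frame(sigma_min_ms = levels[i] * 1000,
                              hwhh_deg = NA, j_peak = NA, est_sd_deg = NA,
                              peak_count = NA, ips = NA)
      next
    }
    mod <- response_model(tun, grid_step = grid_step)
    fi <- fisher_information(mod)
    j_peak <- max(fi$j_expectation)
    peak_count <- max(mod$lambda_hat)
    rows[[i]] <- data.frame(sigma_min_ms = levels[i] * 1000,
                            hwhh_deg = tun$hwhh_deg, j_peak = j_peak,
                            est_sd_deg = 1 / sqrt(j_peak),
                            peak_count = peak_count,
                            ips = j_peak / peak_count)
  }
  by_level <- do.call(rbind, rows)
  ok <- is.finite(by_level$ips)
  qc <- NULL; vertex <- NA_real_; interior <- FALSE
  if (sum(ok) >= 3) {
    qf <- lm(ips ~ sigma_min_ms + I(sigma_min_ms^2), by_level[ok, ])
    qc <- coef(qf)
    if (is.finite(qc[3]) && qc[3] < 0) {
      vertex <- unname(-qc[2] / (2 * qc[3]))
      interior <- vertex > min(by_level$sigma_min_ms[ok]) &&
        vertex < max(by_level$sigma_min_ms[ok])
    }
  }
  argmax <- by_level$sigma_min_ms[ok][which.max(by_level$ips[ok])]
  structure(list(by_level = by_level, quad = qc, vertex_ms = vertex,
                 vertex_interior = interior, argmax_ms = argmax,
                 tunings = tunings),
            class = "info_result")
}

#' Information-per-spike surfaces over a tuning-width sweep
#'
#' @param counts data.frame with `width_scale` (jitter-profile width
#'   multiplier or realised width id), `sigma_min_s`, `direction_deg`,
#'   `spike_count`.
#' @return object of class `width_sweep_result`: `per_width` data.frame
#'   (width_scale, hwhh_low_jitter_deg, optimal_sigma_ms, interior_peak),
#'   `curves` (list of normalised IPS curves).
#' @export
width_sweep <- function(counts) {
  widths <- sort(unique(counts$width_scale))
  per <- vector("list", length(widths))
  curves <- vector("list", length(widths))
  for (i in seq_along(widths)) {
    d <- counts[counts$width_scale == widths[i], ]
    eff <- efficiency_analysis(d)
    bl <- eff$by_level
    ok <- is.finite(bl$ips)
    norm_ips <- bl$ips / max(bl$ips[ok])
    curves[[i]] <- data.frame(width_scale = widths[i],
                              sigma_min_ms = bl$sigma_min_ms,
                              ips_norm = norm_ips)
    lows <- which(ok)
    hwhh_low <- bl$hwhh_deg[lows[which.min(bl$sigma_min_ms[lows])]]
    # interior optimum: the measured argmax is not at a sweep boundary and
    # the quadratic opens downward with an interior vertex
    at_boundary <- eff$argmax_ms %in% range(bl$sigma_min_ms[ok])
    per[[i]] <- data.frame(width_scale = widths[i],
                           hwhh_low_jitter_deg = hwhh_low,
                           optimal_sigma_ms = eff$argmax_ms,
                           vertex_ms = eff$vertex_ms,
                           interior_peak = eff$vertex_interior &&
                             !at_boundary)
  }
  structure(list(per_width = do.call(rbind, per), curves = curves),
            class = "width_sweep_result")
}

#' Poisson dispersion check of per-direction spike counts
#'
#' For each direction, the dispersion statistic `(n-1) * var / mean` is
#' compared against its chi-squared null; the fraction of directions
#' rejected at `alpha` is reported (the Poisson response model is verified,
#' and deviations are reported rather than hidden).
#'
#' @param counts data.frame with `direction_deg`, `spike_count`.
#' @param alpha test level per direction.
#' @return list: `per_direction` data.frame with dispersion and p-values,
#'   `fraction_rejected`.
#' @export
poisson_dispersion_check <- function(counts, alpha = 0.01) {
  per <- do.call(rbind, lapply(split(counts, counts$direction_deg),
                               function(d) {
    n <- nrow(d); m <- mean(d$spike_count); v <- var(d$spike_count)
    if (m <= 0 || n < 3)
      return(data.frame(direction_deg = d$direction_deg[1],
                        dispersion = NA_real_, p = NA_real_))
    stat <- (n - 1) * v / m
    p <- 2 * min(stats::pchisq(stat, n - 1),
                 stats::pchisq(stat, n - 1, lower.tail = FALSE))
    data.frame(direction_deg = d$direction_deg[1], dispersion = v / m, p = p)
  }))
  ok <- is.finite(per$p)
  list(per_direction = per,
       fraction_rejected = mean(per$p[ok] < alpha))
}
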