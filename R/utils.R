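#' Unit vector of grating drift
#'
#' Direction convention: 0 degrees is a vertical grating drifting rightward
#' (drift along +azimuth), 90 degrees a horizontal grating drifting downward
#' (drift along -elevation), and so on anticlockwise in stimulus angle.
#'
#' @param direction_deg stimulus direction in degrees.
#' @return length-2 numeric (azimuth, elevation components).
#' @keywords internal
drift_unit <- function(direction_deg) {
  th <- direction_deg * pi / 180
  c(cos(th), -sin(th))
}

#' Wrapped angular distance on the orientation (180-degree periodic) circle
#'
#' @param theta,ref directions in degrees.
#' @return distance in degrees, in \[0, 90\].
#' @keywords internal
dist180 <- function(theta, ref) {
  d <- (theta - ref) %% 180
  pmin(d, 180 - d)
}

#' Fold spike times back into the trial window by whole stimulus periods
#'
#' The drifting grating is steady-state periodic, so a spike pushed past the
#' trial boundary by a latency shift is phase-equivalent to one a whole number
#' of periods earlier. Folding preserves both spike count and stimulus phase.
#'
#' @param t spike times (s).
#' @param period stimulus period (s).
#' @param duration trial duration (s).
#' @param boundary "wrap" folds by whole periods; "truncate" drops
#'   out-of-window spikes.
#' @return numeric vector of times in \[0, duration\].
#' @keywords internal
wrap_times <- function(t, period, duration, boundary = c("wrap", "truncate")) {
  boundary <- match.arg(boundary)
  if (boundary == "truncate") return(t[t >= 0 & t <= duration])
  hi <- t > duration
  if (any(hi)) t[hi] <- t[hi] - period * ceiling((t[hi] - duration) / period)
  lo <- t < 0
  if (any(lo)) t[lo] <- t[lo] + period * ceiling(-t[lo] / period)
  # guard against landing exactly on duration + eps through float error
  pmin(pmax(t, 0), duration)
}

#' Deterministic stage seed derived from a master seed
#'
#' Every stochastic stage draws its seed from the run's master seed and the
#' stage name, so a single integer reproduces the whole experiment.
#'
#' @param master integer master seed.
#' @param stage character stage label.
#' @return integer seed in \[1, 2^31 - 2\].
#' @export
derive_seed <- function(master, stage) {
  m <- 2147483647
  h <- 0
  for (k in utf8ToInt(stage)) h <- (h * 31 + k) %% m
  as.integer((abs(as.numeric(master)) %% m * 48271 + h) %% (m - 1) + 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
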