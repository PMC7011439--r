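# Synthetic 25 Hz tri-axial accelerometer stream driven by the behavioural
# schedule of a simulated track. The sway axis carries a tailbeat sinusoid
# whose amplitude is chosen per state so that realised mean ODBA falls at
# the configured per-state target (mean |A sin| = 2A/pi); resting states
# carry sensor noise only. Depth and temperature follow a smooth
# bathymetry/thermocline model along the true path: depth rises from reef
# to channel with distance from the nearest reef, and temperature declines
# logistically with depth (deeper is never warmer).

#' Bathymetry and thermocline environment model
#'
#' @param x,y positions (m) on the site plane.
#' @param reefs two-column matrix of reef-centre coordinates (m).
#' @param config a [sim_config()].
#' @return `bathy_depth`: depth (m); `thermocline_temp`: temperature (C).
#' @export
bathy_depth <- function(x, y, reefs, config) {
  dmin <- rep(Inf, length(x))
  for (i in seq_len(nrow(reefs))) {
    dmin <- pmin(dmin, sqrt((x - reefs[i, 1])^2 + (y - reefs[i, 2])^2))
  }
  s <- pmin(pmax(dmin / config$bathy_scale_m, 0), 1)
  sm <- s^2 * (3 - 2 * s) # smoothstep
  z <- config$reef_depth_m + (config$channel_depth_m - config$reef_depth_m) * sm
  pmin(pmax(z, config$depth_range_m[1]), config$depth_range_m[2])
}

#' @rdname bathy_depth
#' @param depth depth (m).
#' @export
thermocline_temp <- function(depth, config) {
  tt <- config$thermo_deep_c +
    (config$thermo_surface_c - config$thermo_deep_c) /
      (1 + exp((depth - config$thermo_mid_m) / config$thermo_width_m))
  pmin(pmax(tt, config$temp_range_c[1]), config$temp_range_c[2])
}

state_amplitude <- function(state, cfg) {
  a <- c(
    shelter_rest = 0, patch_rest = 0,
    transit = cfg$odba_transit_g * pi / 2,
    patch_moderate = cfg$odba_moderate_g * pi / 2,
    patch_burst = cfg$odba_burst_g * pi / 2
  )
  unname(a[state])
}

#' Simulate a 25 Hz tri-axial accelerometer stream from ground truth
#'
#' @param truth the `truth` element of [simulate_night_track()].
#' @param config the same [sim_config()] used for the track.
#' @param window optional `c(start, end)` (POSIXct) restricting the stream
#'   to a sub-interval of the schedule (e.g. one night).
#' @return data.frame at `accel_rate_hz`: `timestamp` (UTC, fractional
#'   seconds), `ax_g` (surge), `ay_g` (sway), `az_g` (heave), `depth_m`,
#'   `temp_c`.
#' @export
simulate_biologger <- function(truth, config, window = NULL) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  sched <- truth$schedule
  if (is.null(sched) || nrow(sched) == 0) {
    stop("simulate_biologger: truth has no behavioural schedule")
  }
  if (any(diff(as.numeric(sched$time)) != 1)) {
    stop("simulate_biologger: schedule does not cover the interval contiguously")
  }
  if (!is.null(window)) {
    keep <- sched$time >= window[1] & sched$time < window[2]
    if (!any(keep)) stop("simulate_biologger: window outside the schedule")
    sched <- sched[keep, , drop = FALSE]
  }
  set.seed(cfg$seed + 500000L)
  fs <- cfg$accel_rate_hz
  n_sec <- nrow(sched)
  n <- n_sec * fs
  t_rel <- (seq_len(n) - 1) / fs

  A_sec <- state_amplitude(sched$state, cfg)
  A <- rep(A_sec, each = fs)
  f <- 1 / cfg$tailbeat_period_s
  phase <- runif(1, 0, 2 * pi)
  dyn_sway <- A * sin(2 * pi * f * t_rel + phase)

  swimming <- rep(A_sec > 0, each = fs)
  pitch_raw <- ifelse(swimming, 0.12, 0)
  # smooth posture transitions over ~2 s
  pitch <- as.numeric(stats::filter(pitch_raw, rep(1 / 49, 49), sides = 2))
  pitch[is.na(pitch)] <- pitch_raw[is.na(pitch)]

  noise <- function() rnorm(n, 0, cfg$noise_sd_g)
  ax <- sin(pitch) + noise()                    # surge: gravity component
  ay <- dyn_sway + noise()                      # sway: tailbeat + noise
  az <- cos(pitch) + noise()                    # heave: gravity component

  # environment along the true path, at 1 Hz, repeated to fs
  pt <- as.numeric(truth$path$time)
  sec_t <- as.numeric(sched$time)
  px <- stats::approx(pt, truth$path$x, xout = sec_t, rule = 2)$y
  py <- stats::approx(pt, truth$path$y, xout = sec_t, rule = 2)$y
  reefs <- rbind(
    as.matrix(truth$shelters[, c("x", "y")]),
    if (nrow(truth$patches)) as.matrix(truth$patches[, c("cx", "cy")]) else NULL,
    c(0, 0)
  )
  depth_sec <- bathy_depth(px, py, reefs, cfg)
  temp_sec <- thermocline_temp(depth_sec, cfg)

  data.frame(
    timestamp = rep(sched$time, each = fs) + rep((seq_len(fs) - 1) / fs, n_sec),
    ax_g = ax, ay_g = ay, az_g = az,
    depth_m = rep(depth_sec, each = fs),
    temp_c = rep(temp_sec, each = fs)
  )
}
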