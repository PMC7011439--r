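#' Simulation configuration for synthetic tracking and biologger data
#'
#' Bundles every tunable of the synthetic-data generator. Defaults emulate
#' the statistical structure of nocturnal demersal-shark tracking at a rocky
#' reef site: daytime shelter rest, departure a few hours after sunset,
#' transit between reefs, 1-3 area-restricted-search patches per night, and
#' a return to a daytime shelter before sunrise. Envelopes follow the field
#' ranges such data show: depths of roughly 1-112 m, temperatures of
#' 10.0-23.8 C, patch radii of 8-112 m, departure 3.4 +/- 2.2 h after
#' sunset and return 3.5 h before sunrise, positional error 5-10 m.
#'
#' @param site_origin `c(lon, lat)` of the site centre (degrees).
#' @param date civil date of the tagging morning (local).
#' @param tz_offset_h local clock offset from UTC in hours.
#' @param start_local_h local clock hour at which the track starts.
#' @param duration_h track duration in hours (>= 24, i.e. one diel cycle).
#' @param n_patches patches per night: integer 0-3, or `NULL` to draw
#'   1-3 with weights 0.79/0.14/0.07 (most nights use a single patch).
#' @param patch_radius_m vector of true patch radii (m), recycled per patch,
#'   or `NULL` to draw log-normally with mean near 30 m, clamped to
#'   `[8, 112]`.
#' @param patch_regime per-patch activity regime `"moderate"`, `"burst"` or
#'   `"rest"`, recycled, or `NULL` to draw with weights 0.54/0.33/0.13.
#' @param transit_speed,patch_speed swimming speeds (m/s) in transit and
#'   inside a patch.
#' @param depart_after_sunset_h,depart_sd_h mean and SD (h) of the departure
#'   offset after sunset (truncated normal).
#' @param leave_before_sunrise_h,leave_sd_h mean and SD (h) of the offset
#'   before sunrise at which the last patch is left.
#' @param residence_h,residence_sd_h mean and SD (h) of per-patch residence
#'   (log-normal, clamped to `[0.3, 5]`).
#' @param tailbeat_period_s full tailbeat period in seconds, within
#'   `[0.5, 2]`.
#' @param odba_rest_g,odba_transit_g,odba_moderate_g,odba_burst_g target
#'   mean ODBA (g) realised per behavioural state.
#' @param burst_prob_per_s per-second probability of starting a burst run in
#'   a burst-regime patch; runs last 1-5 s.
#' @param noise_sd_g accelerometer sensor noise SD (g) per axis.
#' @param detection_error_sd_m isotropic positional error SD (m) added per
#'   coordinate to each detection.
#' @param sample_interval_s detection interval (s).
#' @param accel_rate_hz accelerometer sampling rate (Hz).
#' @param depth_range_m,temp_range_c site envelopes used to clamp the
#'   environment model.
#' @param reef_depth_m,channel_depth_m,bathy_scale_m bathymetry model:
#'   depth rises smoothly from `reef_depth_m` on a reef to
#'   `channel_depth_m` in channels over `bathy_scale_m` metres.
#' @param thermo_surface_c,thermo_deep_c,thermo_mid_m,thermo_width_m
#'   logistic thermocline: temperature declines from surface to deep value
#'   with midpoint depth and width in metres.
#' @param shark_id identifier written into generated streams.
#' @param seed integer RNG seed; identical config + seed gives identical
#'   output.
#' @return object of class `sim_config` (a validated list).
#' @export
sim_config <- function(site_origin = c(-118.49, 33.445),
                       date = "2017-08-09",
                       tz_offset_h = -7,
                       start_local_h = 9,
                       duration_h = 24,
                       n_patches = NULL,
                       patch_radius_m = NULL,
                       patch_regime = NULL,
                       transit_speed = 0.35,
                       patch_speed = 0.25,
                       depart_after_sunset_h = 3.4,
                       depart_sd_h = 2.2,
                       leave_before_sunrise_h = 3.5,
                       leave_sd_h = 2.6,
                       residence_h = 2.3,
                       residence_sd_h = 2.0,
                       tailbeat_period_s = 1.0,
                       odba_rest_g = 0.03,
                       odba_transit_g = 1.0,
                       odba_moderate_g = 0.8,
                       odba_burst_g = 2.5,
                       burst_prob_per_s = 0.03,
                       noise_sd_g = 0.01,
                       detection_error_sd_m = 7.5,
                       sample_interval_s = 2,
                       accel_rate_hz = 25,
                       depth_range_m = c(1, 112),
                       temp_range_c = c(10.0, 23.8),
                       reef_depth_m = 6,
                       channel_depth_m = 35,
                       bathy_scale_m = 300,
                       thermo_surface_c = 21,
                       thermo_deep_c = 12,
                       thermo_mid_m = 25,
                       thermo_width_m = 8,
                       shark_id = "SIM01",
                       seed = 1) {
  cfg <- as.list(environment())
  stopifnot(
    length(cfg$site_origin) == 2,
    cfg$duration_h >= 24,
    cfg$transit_speed > 0, cfg$patch_speed > 0,
    cfg$tailbeat_period_s >= 0.5, cfg$tailbeat_period_s <= 2,
    cfg$sample_interval_s > 0, cfg$accel_rate_hz > 0,
    diff(cfg$depth_range_m) > 0, diff(cfg$temp_range_c) > 0,
    cfg$detection_error_sd_m >= 0,
    cfg$odba_rest_g < cfg$odba_moderate_g,
    cfg$odba_moderate_g <= cfg$odba_burst_g
  )
  if (!is.null(cfg$n_patches)) {
    stopifnot(cfg$n_patches >= 0, cfg$n_patches <= 3)
  }
  if (!is.null(cfg$patch_radius_m)) {
    stopifnot(all(cfg$patch_radius_m >= 8), all(cfg$patch_radius_m <= 112))
  }
  if (!is.null(cfg$patch_regime)) {
    stopifnot(all(cfg$patch_regime %in% c("moderate", "burst", "rest")))
  }
  class(cfg) <- "sim_config"
  cfg
}

# truncated-normal draw by rejection (clamped fallback keeps it finite)
rtnorm1 <- function(mean, sd, lo, hi) {
  for (i in 1:50) {
    x <- rnorm(1, mean, sd)
    if (x >= lo && x <= hi) return(x)
  }
  min(max(mean, lo), hi)
}

draw_patch_radius <- function(n) {
  pmin(pmax(rlnorm(n, meanlog = log(28), sdlog = 0.6), 8), 112)
}

draw_regimes <- function(n) {
  sample(c("moderate", "burst", "rest"), n, replace = TRUE,
         prob = c(0.54, 0.33, 0.13))
}
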