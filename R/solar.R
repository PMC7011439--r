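# NOAA solar geometry (Julian-century ephemeris, zenith 90.833 degrees for
# the solar limb + refraction). Times are computed in UTC with one
# refinement iteration, giving accuracy of about half a minute at
# mid-latitudes; local clock times are a presentation concern handled by an
# explicit UTC offset.

deg2rad <- function(d) d * pi / 180
rad2deg <- function(r) r * 180 / pi

# Equation of time (minutes) and solar declination (radians) at Julian
# century jc.
solar_ephemeris <- function(jc) {
  L0 <- (280.46646 + jc * (36000.76983 + 0.0003032 * jc)) %% 360
  M <- 357.52911 + jc * (35999.05029 - 0.0001537 * jc)
  e <- 0.016708634 - jc * (0.000042037 + 0.0000001267 * jc)
  C <- sin(deg2rad(M)) * (1.914602 - jc * (0.004817 + 0.000014 * jc)) +
    sin(deg2rad(2 * M)) * (0.019993 - 0.000101 * jc) +
    sin(deg2rad(3 * M)) * 0.000289
  true_long <- L0 + C
  omega <- 125.04 - 1934.136 * jc
  lambda <- true_long - 0.00569 - 0.00478 * sin(deg2rad(omega))
  eps0 <- 23 + (26 + (21.448 - jc * (46.815 + jc * (0.00059 - jc * 0.001813))) / 60) / 60
  eps <- eps0 + 0.00256 * cos(deg2rad(omega))
  decl <- asin(sin(deg2rad(eps)) * sin(deg2rad(lambda)))
  y <- tan(deg2rad(eps) / 2)^2
  eqtime <- 4 * rad2deg(
    y * sin(2 * deg2rad(L0)) - 2 * e * sin(deg2rad(M)) +
      4 * e * y * sin(deg2rad(M)) * cos(2 * deg2rad(L0)) -
      0.5 * y^2 * sin(4 * deg2rad(L0)) - 1.25 * e^2 * sin(2 * deg2rad(M))
  )
  list(eqtime = eqtime, decl = decl)
}

# Hour angle (degrees) of the sun at the given zenith; NA outside [-1, 1].
sunrise_hour_angle <- function(lat, decl, zenith = 90.833) {
  phi <- deg2rad(lat)
  cosha <- cos(deg2rad(zenith)) / (cos(phi) * cos(decl)) - tan(phi) * tan(decl)
  if (abs(cosha) > 1) return(NA_real_)
  rad2deg(acos(cosha))
}

#' Sunrise and sunset times
#'
#' Computes local sunrise and sunset for a date and location from NOAA solar
#' geometry (zenith 90.833 degrees). Diel splitting of tracks and all
#' "hours after sunset" quantities are anchored to these times.
#'
#' @param date a `Date` (or string coercible to one), the civil date at the
#'   site in local time.
#' @param lon,lat location in degrees.
#' @param tz_offset_h offset of local clock from UTC in hours (e.g. -7 for
#'   Pacific daylight time); used both to interpret `date` and to report
#'   `sunrise_local`/`sunset_local`.
#' @return list with `sunrise`, `sunset` (`POSIXct`, UTC) and
#'   `sunrise_local`, `sunset_local` (`POSIXct` shifted by `tz_offset_h`,
#'   still labelled UTC).
#' @export
solar_times <- function(date, lon, lat, tz_offset_h = 0) {
  if (abs(lat) >= 66) stop("solar_times: polar day/night latitudes unsupported")
  date <- as.Date(date)
  # Julian day at local civil noon
  jd <- as.numeric(date) + 2440587.5 + (12 - tz_offset_h) / 24
  one <- function(target_min) {
    # target_min: function(eph, ha) -> minutes after 0h UTC of the date
    t_min <- 720
    for (i in 1:3) {
      jc <- (jd - 2451545 + (t_min - 720) / 1440) / 36525
      eph <- solar_ephemeris(jc)
      ha <- sunrise_hour_angle(lat, eph$decl)
      if (is.na(ha)) stop("solar_times: sun does not rise/set on this date")
      t_min <- target_min(eph, ha)
    }
    t_min
  }
  rise_min <- one(function(eph, ha) 720 - 4 * (lon + ha) - eph$eqtime)
  set_min <- one(function(eph, ha) 720 - 4 * (lon - ha) - eph$eqtime)
  # rise_min/set_min are minutes after 0h UTC of the civil date. For the
  # westerly longitudes this package targets, the UTC day containing the
  # local morning equals the local civil date.
  base <- as.POSIXct(as.numeric(date) * 86400, origin = "1970-01-01", tz = "UTC")
  list(
    sunrise = base + rise_min * 60,
    sunset = base + set_min * 60,
    sunrise_local = base + (rise_min + tz_offset_h * 60) * 60,
    sunset_local = base + (set_min + tz_offset_h * 60) * 60
  )
}
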