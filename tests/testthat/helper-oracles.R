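# Independent oracles and small fixture builders used across the suite.

# low-precision solar ephemeris (Fourier-series equation of time and
# declination), independent of the package's Julian-century computation
oracle_solar <- function(date, lon, lat) {
  doy <- as.integer(strftime(as.Date(date), "%j"))
  gam <- 2 * pi / 365 * (doy - 1 + 0.5)
  eqtime <- 229.18 * (0.000075 + 0.001868 * cos(gam) - 0.032077 * sin(gam) -
                        0.014615 * cos(2 * gam) - 0.040849 * sin(2 * gam))
  decl <- 0.006918 - 0.399912 * cos(gam) + 0.070257 * sin(gam) -
    0.006758 * cos(2 * gam) + 0.000907 * sin(2 * gam) -
    0.002697 * cos(3 * gam) + 0.00148 * sin(3 * gam)
  phi <- lat * pi / 180
  cosha <- cos(90.833 * pi / 180) / (cos(phi) * cos(decl)) - tan(phi) * tan(decl)
  ha <- acos(cosha) * 180 / pi
  base <- as.POSIXct(as.numeric(as.Date(date)) * 86400,
                     origin = "1970-01-01", tz = "UTC")
  list(
    sunrise = base + (720 - 4 * (lon + ha) - eqtime) * 60,
    sunset = base + (720 - 4 * (lon - ha) - eqtime) * 60
  )
}

# densified brute-force first passage time: path resampled at `step_m`
# spacing, crossings located by the first dense sample beyond the radius
oracle_fpt <- function(x, y, tt, i, r, step_m = 0.01) {
  seg_len <- sqrt(diff(x)^2 + diff(y)^2)
  dx <- list(); dy <- list(); dtt <- list()
  for (k in seq_along(seg_len)) {
    m <- max(2L, ceiling(seg_len[k] / step_m))
    a <- seq(0, 1, length.out = m + 1)[-(m + 1)]
    dx[[k]] <- x[k] + a * (x[k + 1] - x[k])
    dy[[k]] <- y[k] + a * (y[k + 1] - y[k])
    dtt[[k]] <- tt[k] + a * (tt[k + 1] - tt[k])
  }
  px <- c(unlist(dx), x[length(x)])
  py <- c(unlist(dy), y[length(y)])
  pt <- c(unlist(dtt), tt[length(tt)])
  ref <- which.min(abs(pt - tt[i]))
  d <- sqrt((px - x[i])^2 + (py - y[i])^2)
  fw <- which(d[ref:length(d)] > r)
  bw <- which(d[ref:1] > r)
  if (!length(fw) || !length(bw)) return(NA_real_)
  pt[ref + fw[1] - 1] - pt[ref - bw[1] + 1]
}

# exhaustive minimal within-segment sum of squares over all partitions of
# 1..n into K segments of length >= Lmin
oracle_partition_sse <- function(x, K, Lmin) {
  n <- length(x)
  cs <- c(0, cumsum(x)); cs2 <- c(0, cumsum(x^2))
  sse <- function(i, j) {
    len <- j - i + 1
    (cs2[j + 1] - cs2[i]) - (cs[j + 1] - cs[i])^2 / len
  }
  best <- Inf
  rec <- function(start, k, acc) {
    if (k == 1) {
      if (n - start + 1 >= Lmin) best <<- min(best, acc + sse(start, n))
      return(invisible())
    }
    for (end in (start + Lmin - 1):(n - (k - 1) * Lmin)) {
      rec(end + 1, k - 1, acc + sse(start, end))
    }
  }
  if (n >= K * Lmin) rec(1, K, 0)
  best
}

# Monte-Carlo area of intersection of two regions given point-in-region
# predicates and a bounding box
oracle_mc_overlap <- function(in_a, in_b, bbox, n = 1e5) {
  px <- runif(n, bbox[1], bbox[2])
  py <- runif(n, bbox[3], bbox[4])
  mean(in_a(px, py) & in_b(px, py)) * (bbox[2] - bbox[1]) * (bbox[4] - bbox[3])
}

# convex polygon (counter-clockwise) with given centre and radii
make_convex_poly <- function(cx, cy, r, nv = 8) {
  th <- sort(runif(nv, 0, 2 * pi))
  cbind(x = cx + r * cos(th), y = cy + r * sin(th))
}

# straight-line track at constant speed (m/s), points every `step` m
straight_track <- function(len = 400, step = 2, v = 1) {
  data.frame(x = seq(0, len, by = step), y = 0,
             t = seq(0, len, by = step) / v)
}

# in-memory detection track
toy_track <- function(n = 10, t0 = as.POSIXct("2017-08-09 16:00:00", tz = "UTC")) {
  data.frame(
    shark_id = "S1",
    timestamp = t0 + (seq_len(n) - 1) * 2,
    lon = -118.49 + seq_len(n) * 1e-5,
    lat = 33.445 + seq_len(n) * 1e-5,
    gain_db = 0,
    signal_db = 90
  )
}

# point-in-convex-polygon test (for MC oracles), even-odd rule
pip <- function(px, py, poly) {
  n <- nrow(poly); inside <- rep(FALSE, length(px)); j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]; xj <- poly[j, 1]; yj <- poly[j, 2]
    cr <- ((yi > py) != (yj > py)) & (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, cr); j <- i
  }
  inside
}
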