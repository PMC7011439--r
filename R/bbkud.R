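# Brownian bridge kernel utilization distributions. The diffusion
# parameter sig1 (m s^-1/2) is estimated by the leave-one-out likelihood in
# which each odd-indexed location is modelled as Normal around the
# time-interpolated position of its neighbours, with variance
# T a(1-a) sig1^2 + ((1-a)^2 + a^2) sig2^2 (a = fractional time). The UD is
# the time-weighted average over consecutive-pair bridges of that Gaussian,
# discretized by numeric integration over the bridge, on a metric grid.

bridge_sd2 <- function(alpha, T, sig1, sig2) {
  T * alpha * (1 - alpha) * sig1^2 + ((1 - alpha)^2 + alpha^2) * sig2^2
}

#' Estimate the Brownian motion variance parameter of a bridge model
#'
#' Maximises the leave-one-out likelihood over `sig1` by 1-D bounded
#' optimisation (Brent) on `[1e-4, 10]` with tolerance 1e-6.
#'
#' @param track projected track: data.frame with `x`, `y` (m) and
#'   `timestamp` (or numeric `t`, seconds).
#' @param sig2 positional error SD in metres (default 7.5, the midpoint of
#'   a 5-10 m receiver accuracy envelope).
#' @return `sig1` in m s^-1/2.
#' @export
estimate_sig1 <- function(track, sig2 = 7.5) {
  if (nrow(track) < 3) stop("estimate_sig1: need at least 3 detections")
  tt <- track_time_s(track)
  x <- track$x; y <- track$y
  mid <- seq(2, nrow(track) - 1, by = 2)
  i0 <- mid - 1; i1 <- mid + 1
  T <- tt[i1] - tt[i0]
  a <- (tt[mid] - tt[i0]) / T
  mux <- (1 - a) * x[i0] + a * x[i1]
  muy <- (1 - a) * y[i0] + a * y[i1]
  negll <- function(sig1) {
    s2 <- bridge_sd2(a, T, sig1, sig2)
    -sum(dnorm(x[mid], mux, sqrt(s2), log = TRUE) +
           dnorm(y[mid], muy, sqrt(s2), log = TRUE))
  }
  opt <- optimize(negll, interval = c(1e-4, 10), tol = 1e-6)
  if (!is.finite(opt$objective)) stop("estimate_sig1: non-finite likelihood")
  opt$minimum
}

track_time_s <- function(track) {
  if (!is.null(track$t)) return(as.numeric(track$t))
  as.numeric(track$timestamp)
}

#' Brownian bridge kernel utilization distribution
#'
#' @param track projected track (`x`, `y` in m, `timestamp` or `t`).
#' @param sig1 Brownian motion parameter (m s^-1/2), e.g. from
#'   [estimate_sig1()].
#' @param sig2 positional error SD (m).
#' @param cell_size_m grid cell size (m); 5 m resolves the smallest core
#'   areas such data produce.
#' @param alpha_steps integration steps per location pair (midpoint rule).
#' @param pad_sd grid padding in multiples of the largest bridge SD.
#' @return object of class `bbkud`: `x`, `y` (cell-centre coordinates),
#'   `z` (matrix of probability mass per cell, rows = x), `cell_size_m`,
#'   `sig1`, `sig2`. Total mass is 1.
#' @export
bbkud <- function(track, sig1, sig2 = 7.5, cell_size_m = 5,
                  alpha_steps = 10, pad_sd = 3) {
  tt <- track_time_s(track)
  if (diff(range(tt)) <= 0) stop("bbkud: degenerate track duration")
  x <- track$x; y <- track$y
  n <- length(x)
  Tp <- diff(tt)
  keep <- Tp > 0
  max_sd <- sqrt(max(bridge_sd2(0.5, max(Tp), sig1, sig2), sig2^2))
  pad <- pad_sd * max_sd
  gx <- seq(min(x) - pad, max(x) + pad + cell_size_m, by = cell_size_m)
  gy <- seq(min(y) - pad, max(y) + pad + cell_size_m, by = cell_size_m)
  z <- matrix(0, length(gx), length(gy))
  al <- (seq_len(alpha_steps) - 0.5) / alpha_steps
  for (i in which(keep)) {
    w <- Tp[i] / alpha_steps
    for (a in al) {
      s2 <- bridge_sd2(a, Tp[i], sig1, sig2)
      mx <- (1 - a) * x[i] + a * x[i + 1]
      my <- (1 - a) * y[i] + a * y[i + 1]
      dx <- dnorm(gx, mx, sqrt(s2))
      dy <- dnorm(gy, my, sqrt(s2))
      z <- z + w * (dx %o% dy)
    }
  }
  z <- z / sum(z)
  structure(
    list(x = gx, y = gy, z = z, cell_size_m = cell_size_m,
         sig1 = sig1, sig2 = sig2),
    class = "bbkud"
  )
}

#' Isopleth contour of a utilization distribution
#'
#' Selects the smallest set of cells whose summed mass reaches the
#' isopleth (cells ranked by density, ties broken in row-major order, so
#' the result is reproducible), reports its area, and extracts boundary
#' polygons by marching squares at the limiting density.
#'
#' @param ud a [bbkud()] (or any list with `x`, `y`, `z`, `cell_size_m`).
#' @param isopleth fraction in (0, 1]; 0.95 estimates daily activity
#'   space, 0.50 the core.
#' @return object of class `ud_contour`: `cells` (logical matrix),
#'   `area_km2`, `isopleth`, `level`, `polygons` (list of two-column
#'   matrices), plus the grid axes.
#' @export
ud_contour <- function(ud, isopleth) {
  stopifnot(isopleth > 0, isopleth <= 1)
  z <- ud$z
  ord <- order(-as.vector(z), seq_along(z))
  cum <- cumsum(as.vector(z)[ord])
  n_need <- which(cum >= isopleth - 1e-12)[1]
  if (is.na(n_need)) n_need <- length(ord)
  sel <- logical(length(z))
  sel[ord[seq_len(n_need)]] <- TRUE
  cells <- matrix(sel, nrow(z), ncol(z))
  level <- as.vector(z)[ord[n_need]]
  polys <- tryCatch({
    cl <- contourLines(ud$x, ud$y, z, levels = level * (1 - 1e-9))
    lapply(cl, function(p) cbind(x = p$x, y = p$y))
  }, error = function(e) list())
  structure(
    list(cells = cells, area_km2 = n_need * ud$cell_size_m^2 / 1e6,
         isopleth = isopleth, level = level, polygons = polys,
         x = ud$x, y = ud$y, cell_size_m = ud$cell_size_m),
    class = "ud_contour"
  )
}

# ---- region machinery (contours and polygons on a common raster) --------

# logical mask of a region over grid points (px, py)
region_mask <- function(region, px, py) {
  if (inherits(region, "ud_contour")) {
    ix <- findInterval(px, region$x - region$cell_size_m / 2)
    iy <- findInterval(py, region$y - region$cell_size_m / 2)
    ok <- ix >= 1 & ix <= length(region$x) & iy >= 1 & iy <= length(region$y)
    out <- logical(length(px))
    out[ok] <- region$cells[cbind(ix[ok], iy[ok])]
    out
  } else {
    polys <- if (is.matrix(region)) list(region) else region
    inside <- logical(length(px))
    for (p in polys) inside <- xor(inside, point_in_poly(px, py, p))
    inside
  }
}

# even-odd (crossing number) point-in-polygon test, vectorised over points
point_in_poly <- function(px, py, poly) {
  n <- nrow(poly)
  if (n < 3) return(rep(FALSE, length(px)))
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    cross <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, cross)
    j <- i
  }
  inside
}

region_bbox <- function(region) {
  if (inherits(region, "ud_contour")) {
    idx <- which(region$cells, arr.ind = TRUE)
    h <- region$cell_size_m / 2
    c(min(region$x[idx[, 1]]) - h, max(region$x[idx[, 1]]) + h,
      min(region$y[idx[, 2]]) - h, max(region$y[idx[, 2]]) + h)
  } else {
    polys <- if (is.matrix(region)) list(region) else region
    xs <- unlist(lapply(polys, function(p) p[, 1]))
    ys <- unlist(lapply(polys, function(p) p[, 2]))
    c(min(xs), max(xs), min(ys), max(ys))
  }
}

# rasterize regions on a shared grid; returns list of masks + cell area
raster_masks <- function(regions, n_cells = 1024) {
  bb <- sapply(regions, region_bbox)
  xr <- c(min(bb[1, ]), max(bb[2, ])); yr <- c(min(bb[3, ]), max(bb[4, ]))
  cell <- max(diff(xr), diff(yr)) / n_cells
  gx <- seq(xr[1] + cell / 2, xr[2], by = cell)
  gy <- seq(yr[1] + cell / 2, yr[2], by = cell)
  pts <- expand.grid(x = gx, y = gy)
  masks <- lapply(regions, function(r) region_mask(r, pts$x, pts$y))
  list(masks = masks, cell_area = cell^2)
}

#' Overlap between two regions
#'
#' Computes the area of geometric intersection of two regions (polygons or
#' UD contours) by rasterization on a shared fine grid, and the percentage
#' of the second region overlapped.
#'
#' @param a,b a `ud_contour`, a two-column polygon matrix, or a list of
#'   such matrices (holes/multiple rings via even-odd rule).
#' @param n_cells raster resolution across the joint bounding box.
#' @return list: `area_km2` (intersection), `percent_of_b`.
#' @export
overlap_area <- function(a, b, n_cells = 1024) {
  rm <- raster_masks(list(a, b), n_cells)
  inter <- sum(rm$masks[[1]] & rm$masks[[2]]) * rm$cell_area
  area_b <- sum(rm$masks[[2]]) * rm$cell_area
  list(
    area_km2 = inter / 1e6,
    percent_of_b = if (area_b > 0) 100 * inter / area_b else 0
  )
}

# shoelace polygon area (m^2)
polygon_area <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}
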