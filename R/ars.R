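# Area-restricted-search detection: first passage time (FPT) over a radius
# sweep, selection of the ARS scale as the radius maximising the variance
# of log FPT (capped by the equivalent-circle radius of the nighttime core
# area), Lavielle penalized-contrast segmentation of the FPT series by
# exact dynamic programming on the within-segment sum of squares, and
# extraction of patch geometry (minimum convex polygons) from ARS segments.

#' First passage time profile
#'
#' For each track point and each radius, the first passage time is the time
#' between the first backward and first forward crossings of the circle of
#' that radius centred on the point, with crossings located by linear
#' interpolation along path segments. Values are `NA` where the path ends
#' before crossing in either direction.
#'
#' @param track projected track (`x`, `y` m; `timestamp` or `t`).
#' @param radii strictly increasing radii in metres, within `[1, 1e4]`.
#' @return object of class `fpt_profile`: `radii`, `fpt` (matrix point x
#'   radius, seconds), `varlog` (per-radius variance of log FPT over
#'   defined values), `time` (per-point timestamps).
#' @export
fpt <- function(track, radii = seq(5, 100, by = 5)) {
  if (any(radii < 1 | radii > 1e4)) stop("fpt: radii outside [1, 1e4] m")
  if (is.unsorted(radii, strictly = TRUE)) stop("fpt: radii must be strictly increasing")
  tt <- track_time_s(track)
  x <- track$x; y <- track$y
  n <- length(x)
  out <- matrix(NA_real_, n, length(radii))
  for (i in seq_len(n)) {
    d <- sqrt((x - x[i])^2 + (y - y[i])^2)
    for (ri in seq_along(radii)) {
      r <- radii[ri]
      tf <- cross_time(d, tt, i, r, forward = TRUE)
      tb <- cross_time(d, tt, i, r, forward = FALSE)
      if (!is.na(tf) && !is.na(tb)) out[i, ri] <- tf - tb
    }
  }
  varlog <- apply(out, 2, function(col) {
    v <- col[is.finite(col) & col > 0]
    if (length(v) < 2) NA_real_ else var(log(v))
  })
  structure(
    list(radii = radii, fpt = out, varlog = varlog, time = tt),
    class = "fpt_profile"
  )
}

# first crossing time of radius r around point i, by linear interpolation
# on the inter-point distance sequence
cross_time <- function(d, tt, i, r, forward = TRUE) {
  n <- length(d)
  if (forward) {
    if (i == n) return(NA_real_)
    idx <- which(d[(i + 1):n] > r)
    if (!length(idx)) return(NA_real_)
    k <- i + idx[1]
    frac <- (r - d[k - 1]) / (d[k] - d[k - 1])
    tt[k - 1] + frac * (tt[k] - tt[k - 1])
  } else {
    if (i == 1) return(NA_real_)
    idx <- which(d[(i - 1):1] > r)
    if (!length(idx)) return(NA_real_)
    k <- i - idx[1]
    frac <- (r - d[k + 1]) / (d[k] - d[k + 1])
    tt[k + 1] - frac * (tt[k + 1] - tt[k])
  }
}

#' Select the ARS scale from an FPT profile
#'
#' Returns the radius maximising the variance of log FPT. When a nighttime
#' core-area size is supplied, the sweep is capped at the equivalent-circle
#' radius `sqrt(area / pi)` (and at 100 m). A flat variance profile
#' (max/min < 1.2) is flagged as low-signal and the maximising radius is
#' still returned.
#'
#' @param profile an [fpt()] profile.
#' @param r50_area_m2 optional nighttime 50% core area (m^2) capping the
#'   searched radii.
#' @param min_defined minimum number of defined FPT values a radius needs
#'   to enter the selection.
#' @return list: `radius`, `varlog` (named by radius), `low_signal`.
#' @export
ars_scale <- function(profile, r50_area_m2 = NULL, min_defined = 10) {
  radii <- profile$radii
  vl <- profile$varlog
  if (!is.null(r50_area_m2)) {
    rmax <- min(100, sqrt(r50_area_m2 / pi))
    keep <- radii <= max(rmax, min(radii))
    radii <- radii[keep]; vl <- vl[keep]
  }
  ndef <- colSums(is.finite(profile$fpt[, profile$radii %in% radii, drop = FALSE]))
  ok <- is.finite(vl) & ndef >= min_defined
  if (!any(ok)) stop("ars_scale: fewer than ", min_defined,
                     " defined FPT values at every radius")
  radii <- radii[ok]; vl <- vl[ok]
  best <- which.max(vl)
  low <- max(vl) / max(min(vl), .Machine$double.eps) < 1.2
  list(radius = radii[best], varlog = setNames(vl, radii), low_signal = low)
}

#' Lavielle penalized-contrast segmentation
#'
#' Exact dynamic-programming partition of a series into K segments
#' minimising the total within-segment sum of squared deviations from
#' segment means, for K = 1..Kmax, with a minimum segment length. The
#' optimal K is chosen from the standardized contrast
#' `J~(K) = (J(K) - J(Kmax)) / (J(1) - J(Kmax))` as the last K whose
#' scaled second difference `D(K) = (J~(K-1) - 2 J~(K) + J~(K+1)) (Kmax-1)`
#' exceeds the threshold S; if none does, K_opt = 1.
#'
#' @param series numeric vector (no NAs; trim undefined ends first).
#' @param Lmin minimum points per segment.
#' @param Kmax maximum number of segments.
#' @param S threshold on the scaled second difference (default 0.75).
#' @return object of class `lavielle_seg`: `K_opt`, `changepoints`
#'   (last index of each segment but the final one, for K_opt),
#'   `segments` (data.frame first/last per segment), `J`, `J_std`, `D`,
#'   `Lmin`, `Kmax`.
#' @export
lavielle_segment <- function(series, Lmin = 10, Kmax = 20, S = 0.75) {
  x <- as.numeric(series)
  if (anyNA(x)) stop("lavielle_segment: series contains NA; trim to the defined core")
  n <- length(x)
  if (n < 2 * Lmin) stop("lavielle_segment: series shorter than 2*Lmin")
  Kmax_eff <- min(Kmax, floor(n / Lmin))
  cs <- c(0, cumsum(x)); cs2 <- c(0, cumsum(x^2))
  # cost of segment (i..j): within sum of squares about the segment mean
  seg_cost <- function(i, j) {
    len <- j - i + 1
    s <- cs[j + 1] - cs[i]
    (cs2[j + 1] - cs2[i]) - s^2 / len
  }
  # cost matrix rows i (start), cols j (end); Inf where j - i + 1 < Lmin
  C <- matrix(Inf, n, n)
  for (i in seq_len(n - Lmin + 1)) {
    j <- (i + Lmin - 1):n
    len <- j - i + 1
    s <- cs[j + 1] - cs[i]
    C[i, j] <- (cs2[j + 1] - cs2[i]) - s^2 / len
  }
  J <- rep(NA_real_, Kmax_eff)
  Jk <- C[1, ] # best cost of 1..j with k segments
  J[1] <- Jk[n]
  back <- matrix(NA_integer_, Kmax_eff, n)
  if (Kmax_eff > 1) {
    for (k in 2:Kmax_eff) {
      newJ <- rep(Inf, n)
      lo <- k * Lmin
      for (j in lo:n) {
        i_opts <- ((k - 1) * Lmin):(j - Lmin)
        vals <- Jk[i_opts] + C[i_opts + 1, j]
        b <- which.min(vals)
        newJ[j] <- vals[b]
        back[k, j] <- i_opts[b]
      }
      Jk <- newJ
      J[k] <- Jk[n]
    }
  }
  denom <- J[1] - J[Kmax_eff]
  if (!is.finite(denom) || denom <= .Machine$double.eps * max(1, abs(J[1]))) {
    J_std <- rep(0, Kmax_eff)
    D <- rep(0, Kmax_eff)
    K_opt <- 1L
  } else {
    J_std <- (J - J[Kmax_eff]) / denom
    D <- rep(NA_real_, Kmax_eff)
    if (Kmax_eff >= 3) {
      for (k in 2:(Kmax_eff - 1)) {
        D[k] <- (J_std[k - 1] - 2 * J_std[k] + J_std[k + 1]) * (Kmax_eff - 1)
      }
    }
    hits <- which(D > S)
    K_opt <- if (length(hits)) max(hits) else 1L
  }
  # backtrack changepoints for K_opt
  cps <- integer(0)
  if (K_opt > 1) {
    j <- n
    for (k in K_opt:2) {
      i <- back[k, j]
      cps <- c(i, cps)
      j <- i
    }
  }
  bounds <- c(0, cps, n)
  segments <- data.frame(
    first = bounds[-length(bounds)] + 1,
    last = bounds[-1]
  )
  structure(
    list(K_opt = as.integer(K_opt), changepoints = cps, segments = segments,
         J = J, J_std = J_std, D = D, Lmin = Lmin, Kmax = Kmax_eff),
    class = "lavielle_seg"
  )
}

#' Extract ARS patches from a segmented FPT series
#'
#' Segments with high mean FPT are ARS segments; adjacent ARS segments are
#' merged. The default `"split"` rule separates segment means into a
#' low-FPT (transit) and a high-FPT (ARS) group by a two-group partition
#' of log segment means, and requires at least a two-fold contrast between
#' the groups — a series whose segments all sit at one level contains no
#' detectable ARS. The alternatives are `"median"` (mean FPT above the
#' whole-series median; splits patches that dominate the series) and
#' `"fraction_of_max"`. Each merged run becomes a
#' patch: member points, minimum convex polygon (area by the shoelace
#' formula), centroid (mean of member coordinates), and residence from
#' first/last member timestamps. Patches with fewer than 3 distinct
#' points get area 0 and a degenerate flag.
#'
#' @param track projected track used for the FPT series (`x`, `y`,
#'   `timestamp`/`t`), rows aligned to `series_index`.
#' @param segmentation a [lavielle_segment()] of the FPT series core.
#' @param fpt_series the FPT values (seconds) the segmentation was run on.
#' @param scale_radius_m the ARS scale radius (recorded per patch).
#' @param series_index mapping from series positions to track rows
#'   (default: first `length(fpt_series)` rows).
#' @param rule ARS-segment rule: `"split"`, `"median"` or
#'   `"fraction_of_max"` (see Details above).
#' @param frac fraction for `rule = "fraction_of_max"`.
#' @param min_contrast minimum high/low group ratio for `rule = "split"`.
#' @param merge_dist_m ARS runs whose member centroids lie within this
#'   distance are one patch revisited, not two patches: the run pair (and
#'   the excursion between them) is merged. Default 3 scale radii, capped
#'   at 100 m.
#' @param min_residence_min ARS runs shorter than this (minutes) are
#'   dropped: patch use involves meaningful residence (observed patch
#'   residences start around 0.2 h), while a brief high-FPT blip is a
#'   pause in transit.
#' @return data.frame of patches (`patch_id`, `first`, `last`, `entry`,
#'   `exit`, `residence_min`, `area_m2`, `cx`, `cy`, `n_points`,
#'   `degenerate`, `scale_radius_m`) with the MCPs in attribute
#'   `polygons`.
#' @export
extract_patches <- function(track, segmentation, fpt_series, scale_radius_m,
                            series_index = seq_along(fpt_series),
                            rule = c("split", "median", "fraction_of_max"),
                            frac = 0.5, min_contrast = 2,
                            merge_dist_m = min(3 * scale_radius_m, 100),
                            min_residence_min = 10) {
  rule <- match.arg(rule)
  tt <- track_time_s(track)
  seg <- segmentation$segments
  seg_mean <- vapply(seq_len(nrow(seg)), function(i) {
    mean(fpt_series[seg$first[i]:seg$last[i]], na.rm = TRUE)
  }, 0)
  empty_patches <- function() {
    out <- data.frame(
      patch_id = character(), first = integer(), last = integer(),
      entry = as.POSIXct(character(), tz = "UTC"),
      exit = as.POSIXct(character(), tz = "UTC"), residence_min = numeric(),
      area_m2 = numeric(), cx = numeric(), cy = numeric(),
      n_points = integer(), degenerate = logical(),
      scale_radius_m = numeric()
    )
    attr(out, "polygons") <- list()
    out
  }
  is_ars <- switch(rule,
    median = seg_mean > median(fpt_series, na.rm = TRUE),
    fraction_of_max = seg_mean > frac * max(fpt_series, na.rm = TRUE),
    split = {
      lm <- log(pmax(seg_mean, 1))
      if (length(seg_mean) < 2 ||
          max(seg_mean) / max(min(seg_mean), 1) < min_contrast) {
        rep(FALSE, length(seg_mean))
      } else {
        km <- kmeans(lm, centers = matrix(range(lm), ncol = 1))
        hi <- which.max(km$centers)
        cl <- km$cluster == hi
        # contrast between the realised groups, not just the extremes
        if (min(seg_mean[cl]) / max(max(seg_mean[!cl]), 1) < min_contrast &&
            mean(seg_mean[cl]) / max(mean(seg_mean[!cl]), 1) < min_contrast) {
          rep(FALSE, length(seg_mean))
        } else cl
      }
    }
  )
  if (!any(is_ars)) return(empty_patches())
  # merge adjacent ARS segments into runs of series positions
  runs <- rle(is_ars)
  ends <- cumsum(runs$lengths)
  starts <- c(1, head(ends, -1) + 1)
  ars_runs <- which(runs$values)
  spans <- lapply(ars_runs, function(rr) {
    c(seg$first[starts[rr]], seg$last[ends[rr]])
  })
  # spatial merge: consecutive runs revisiting the same place are one patch
  run_centroid <- function(sp) {
    idx <- series_index[sp[1]:sp[2]]
    c(mean(track$x[idx]), mean(track$y[idx]))
  }
  i <- 1
  while (i < length(spans)) {
    c1 <- run_centroid(spans[[i]]); c2 <- run_centroid(spans[[i + 1]])
    if (sqrt(sum((c1 - c2)^2)) <= merge_dist_m) {
      spans[[i]] <- c(spans[[i]][1], spans[[i + 1]][2])
      spans[[i + 1]] <- NULL
    } else {
      i <- i + 1
    }
  }
  # drop blips shorter than the residence floor
  if (length(spans)) {
    dur_min <- vapply(spans, function(sp) {
      idx <- series_index[c(sp[1], sp[2])]
      (tt[idx[2]] - tt[idx[1]]) / 60
    }, 0)
    spans <- spans[dur_min >= min_residence_min]
  }
  if (!length(spans)) return(empty_patches())
  # boundary refinement: a span can bleed into the approach or departure
  # transit; trim leading/trailing member points beyond trim_factor scale
  # radii of the FPT-weighted span centroid (interior excursions stay)
  trim_factor <- 2.5
  spans <- lapply(spans, function(sp) {
    ss <- sp[1]:sp[2]
    idx <- series_index[ss]
    w <- fpt_series[ss]
    w[!is.finite(w)] <- 0
    if (sum(w) <= 0) return(sp)
    cw <- c(sum(track$x[idx] * w), sum(track$y[idx] * w)) / sum(w)
    d <- sqrt((track$x[idx] - cw[1])^2 + (track$y[idx] - cw[2])^2)
    inside <- which(d <= trim_factor * scale_radius_m)
    if (!length(inside)) return(sp)
    c(ss[inside[1]], ss[inside[length(inside)]])
  })
  rows <- list(); polys <- list()
  for (ri in seq_along(spans)) {
    first_s <- spans[[ri]][1]
    last_s <- spans[[ri]][2]
    idx <- series_index[first_s:last_s]
    px <- track$x[idx]; py <- track$y[idx]
    pts <- unique(cbind(px, py))
    degen <- nrow(pts) < 3
    area <- 0
    poly <- NULL
    if (!degen) {
      h <- chull(pts)
      poly <- pts[h, , drop = FALSE]
      area <- polygon_area(poly)
      if (area == 0) degen <- TRUE
    }
    t_entry <- tt[idx[1]]; t_exit <- tt[idx[length(idx)]]
    rows[[ri]] <- data.frame(
      patch_id = sprintf("patch_%02d", ri),
      first = first_s, last = last_s,
      entry = as.POSIXct(t_entry, origin = "1970-01-01", tz = "UTC"),
      exit = as.POSIXct(t_exit, origin = "1970-01-01", tz = "UTC"),
      residence_min = (t_exit - t_entry) / 60,
      area_m2 = area, cx = mean(px), cy = mean(py),
      n_points = length(idx), degenerate = degen,
      scale_radius_m = scale_radius_m
    )
    polys[[ri]] <- poly
  }
  out <- do.call(rbind, rows)
  attr(out, "polygons") <- polys
  out
}

#' Straight-line distances between shelters and patches
#'
#' Leg 1: daytime shelter centroid to first patch; legs between successive
#' patches; final leg: last patch to the next morning's shelter. Distances
#' are Euclidean on the projected plane (site-scale tracks, where planar
#' and great-circle distances agree to within 0.1%).
#'
#' @param patches patch table with `cx`, `cy` (projected m), ordered by
#'   entry time.
#' @param shelter_from `c(x, y)` of the evening shelter centroid.
#' @param shelter_to `c(x, y)` of the next morning's shelter centroid
#'   (optional).
#' @return data.frame: `leg`, `from`, `to`, `distance_m`.
#' @export
patch_distances <- function(patches, shelter_from, shelter_to = NULL) {
  stopifnot(nrow(patches) >= 1)
  pts <- rbind(shelter_from, as.matrix(patches[, c("cx", "cy")]))
  labs <- c("shelter_am", patches$patch_id)
  if (!is.null(shelter_to)) {
    pts <- rbind(pts, shelter_to)
    labs <- c(labs, "shelter_pm")
  }
  d <- sqrt(rowSums((pts[-1, , drop = FALSE] - pts[-nrow(pts), , drop = FALSE])^2))
  data.frame(
    leg = seq_along(d),
    from = labs[-length(labs)], to = labs[-1],
    distance_m = d
  )
}
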