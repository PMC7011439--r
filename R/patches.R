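# Patch activity typing: join spatial patches to per-second activity over
# [entry, exit] and classify each patch as resting, episodic burst
# activity, or moderate consistent activity. Resting patches are excluded
# from downstream patch statistics (a shark motionless for >= 95% of the
# time may simply be sheltering, not using a resource patch).

#' Join patches with per-second activity
#'
#' Aggregates the binary activity states, ODBA, depth and temperature over
#' each patch's [entry, exit] interval. Burst runs are contiguous runs of
#' per-second ODBA at or above `burst_g` lasting `burst_len_s[1]` to
#' `burst_len_s[2]` seconds. A patch whose activity coverage has gaps
#' exceeding `max_gap_frac` of its duration is flagged and later excluded
#' from classification rather than imputed.
#'
#' @param patches patch table (see [extract_patches()]) with `patch_id`,
#'   `entry`, `exit`.
#' @param activity per-second data.frame: `time`, `state`
#'   ("resting"/"active"), `odba_g`, and optionally `depth_m`, `temp_c`.
#' @param burst_g per-second ODBA threshold (g) defining a burst.
#' @param burst_len_s inclusive run-length window (s) for a burst run.
#' @param max_gap_frac maximum tolerated fraction of missing seconds.
#' @return data.frame `patch_activity`: per patch `pct_resting`,
#'   `odba_mean_g`, `odba_max_g`, `burst_count`, `burst_total_s`,
#'   `depth_range_m`, `temp_mean_c`, `coverage`, `coverage_gap`,
#'   `pct_odba_below` (share of seconds under 0.2 g).
#' @export
join_patch_activity <- function(patches, activity, burst_g = 2,
                                burst_len_s = c(1, 5), max_gap_frac = 0.05) {
  at <- as.numeric(activity$time)
  rows <- lapply(seq_len(nrow(patches)), function(i) {
    t0 <- as.numeric(patches$entry[i]); t1 <- as.numeric(patches$exit[i])
    sel <- at >= t0 & at <= t1
    n <- sum(sel)
    expected <- floor(t1 - t0) + 1
    coverage <- n / expected
    a <- activity[sel, , drop = FALSE]
    runs <- rle(a$odba_g >= burst_g)
    bl <- runs$lengths[runs$values]
    bursts <- bl[bl >= burst_len_s[1] & bl <= burst_len_s[2]]
    data.frame(
      patch_id = patches$patch_id[i],
      n_seconds = n,
      coverage = coverage,
      coverage_gap = coverage < 1 - max_gap_frac,
      pct_resting = if (n) 100 * mean(a$state == "resting") else NA_real_,
      pct_odba_below = if (n) 100 * mean(a$odba_g < 0.2) else NA_real_,
      odba_mean_g = if (n) mean(a$odba_g) else NA_real_,
      odba_max_g = if (n) max(a$odba_g) else NA_real_,
      burst_count = length(bursts),
      burst_total_s = sum(bursts),
      depth_range_m = if (n && !is.null(a$depth_m)) diff(range(a$depth_m)) else NA_real_,
      temp_mean_c = if (n && !is.null(a$temp_c)) mean(a$temp_c) else NA_real_
    )
  })
  do.call(rbind, rows)
}

#' Classify patch activity patterns
#'
#' A covered patch is `resting` iff it was motionless for at least
#' `rest_floor`% of the time, per-second ODBA stayed below `odba_rest_g`
#' for at least `rest_floor`% of seconds, and the within-patch depth range
#' is below `depth_flat_m` (no discernible depth change). Otherwise it is
#' active: `episodic_burst` iff it contains at least one burst run (high
#' ODBA sustained 1-5 s) while still resting at least `burst_rest_floor`%
#' of the time, else `moderate_active` (consistent moderate-to-high ODBA).
#' Patches with coverage gaps are classed `excluded`; resting patches are
#' flagged `excluded_from_stats`.
#'
#' @param pa a [join_patch_activity()] table.
#' @param rest_floor percent-motionless floor for the resting class.
#' @param odba_rest_g confirmation ODBA ceiling (g) for resting.
#' @param depth_flat_m depth-range ceiling (m) operationalising "no
#'   discernible changes in depth".
#' @param burst_rest_floor minimum percent resting for the episodic class.
#' @return `pa` with columns `class` (resting / episodic_burst /
#'   moderate_active / excluded) and `excluded_from_stats`.
#' @export
classify_patch <- function(pa, rest_floor = 95, odba_rest_g = 0.2,
                           depth_flat_m = 1.0, burst_rest_floor = 30) {
  cls <- character(nrow(pa))
  for (i in seq_len(nrow(pa))) {
    if (isTRUE(pa$coverage_gap[i]) || pa$n_seconds[i] == 0) {
      cls[i] <- "excluded"
    } else if (pa$pct_resting[i] >= rest_floor &&
               pa$pct_odba_below[i] >= rest_floor &&
               (is.na(pa$depth_range_m[i]) || pa$depth_range_m[i] < depth_flat_m)) {
      cls[i] <- "resting"
    } else if (pa$burst_count[i] >= 1 && pa$pct_resting[i] >= burst_rest_floor) {
      cls[i] <- "episodic_burst"
    } else {
      cls[i] <- "moderate_active"
    }
  }
  pa$class <- cls
  pa$excluded_from_stats <- cls %in% c("resting", "excluded")
  pa
}

#' Patch-use summaries
#'
#' Per-night and cohort summaries of classified patches: counts by class,
#' residence statistics, MCP area statistics, and (when per-night sunset
#' and sunrise columns are present) the arrival offset of the first patch
#' after sunset and the departure offset of the last patch before sunrise.
#'
#' @param patch_table data.frame combining patch geometry and activity:
#'   must contain `patch_id`, `class`, `residence_min`; optionally
#'   `area_m2`, `night`, `entry`, `exit`, `sunset`, `sunrise`.
#' @return list: `by_class`, `n_active`, `residence_h`, `area_m2`,
#'   `arrival_after_sunset_h`, `departure_before_sunrise_h` (each a
#'   `c(mean, sd, min, max)` or `NULL` when the inputs lack the columns).
#' @export
patch_summary <- function(patch_table) {
  pt <- patch_table
  if (nrow(pt) == 0) {
    return(list(by_class = table(character()), n_active = 0,
                residence_h = NULL, area_m2 = NULL,
                arrival_after_sunset_h = NULL,
                departure_before_sunrise_h = NULL))
  }
  stats4 <- function(v) {
    v <- v[is.finite(v)]
    if (!length(v)) return(NULL)
    c(mean = mean(v), sd = if (length(v) > 1) sd(v) else NA, min = min(v), max = max(v))
  }
  active <- pt[!pt$class %in% c("resting", "excluded"), , drop = FALSE]
  arr <- dep <- NULL
  if (!is.null(pt$night) && !is.null(pt$sunset)) {
    firsts <- pt[!duplicated(pt$night), , drop = FALSE]
    arr <- stats4((as.numeric(firsts$entry) - as.numeric(firsts$sunset)) / 3600)
  }
  if (!is.null(pt$night) && !is.null(pt$sunrise)) {
    lasts <- pt[rev(!duplicated(rev(pt$night))), , drop = FALSE]
    dep <- stats4((as.numeric(lasts$sunrise) - as.numeric(lasts$exit)) / 3600)
  }
  list(
    by_class = table(pt$class),
    n_active = nrow(active),
    residence_h = stats4(active$residence_min / 60),
    area_m2 = if (!is.null(active$area_m2)) stats4(active$area_m2) else NULL,
    arrival_after_sunset_h = arr,
    departure_before_sunrise_h = dep
  )
}

#' Overlap of merged patch area with merged core activity space
#'
#' Unions the patch MCPs and the nighttime 50% contours on a shared
#' raster and reports both merged areas, their intersection, and the
#' percent of the core overlapped by patches.
#'
#' @param patch_polys list of two-column MCP matrices (projected m).
#' @param core_contours list of `ud_contour` objects (nighttime 50%).
#' @param n_cells raster resolution.
#' @return list: `patch_area_km2`, `core_area_km2`, `overlap_km2`,
#'   `percent_of_core`.
#' @export
core_overlap <- function(patch_polys, core_contours, n_cells = 1024) {
  regions <- c(patch_polys, core_contours)
  rm <- raster_masks(regions, n_cells)
  np <- length(patch_polys)
  pm <- Reduce(`|`, rm$masks[seq_len(np)])
  cm <- Reduce(`|`, rm$masks[np + seq_along(core_contours)])
  inter <- sum(pm & cm) * rm$cell_area
  core <- sum(cm) * rm$cell_area
  list(
    patch_area_km2 = sum(pm) * rm$cell_area / 1e6,
    core_area_km2 = core / 1e6,
    overlap_km2 = inter / 1e6,
    percent_of_core = if (core > 0) 100 * inter / core else 0
  )
}
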