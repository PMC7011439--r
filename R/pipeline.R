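# Convenience wrappers chaining the analysis stages the way a nighttime
# movement path is actually processed: activity-space estimation from the
# filtered track, then FPT -> scale selection -> Lavielle segmentation ->
# patch extraction on the thinned night path.

#' Diel activity space from a projected track
#'
#' Estimates sig1 by leave-one-out likelihood, builds the Brownian bridge
#' UD and returns the requested isopleth contours and areas.
#'
#' @param track projected track (`x`, `y` m, `timestamp`/`t`).
#' @param isopleths isopleth fractions (default daily 0.95 and core 0.50).
#' @param sig2 positional error SD (m).
#' @param cell_size_m UD grid cell size.
#' @param thin_s optional thinning interval (s) applied before the UD to
#'   keep the bridge integration affordable on long tracks.
#' @return list: `sig1`, `ud`, `contours` (named by isopleth),
#'   `areas_km2` (named vector).
#' @export
activity_space <- function(track, isopleths = c(0.5, 0.95), sig2 = 7.5,
                           cell_size_m = 5, thin_s = NULL) {
  tr <- if (is.null(thin_s)) track else thin_track(track, thin_s)
  s1 <- estimate_sig1(tr, sig2)
  ud <- bbkud(tr, s1, sig2, cell_size_m)
  cts <- lapply(isopleths, function(p) ud_contour(ud, p))
  names(cts) <- as.character(isopleths)
  list(
    sig1 = s1, ud = ud, contours = cts,
    areas_km2 = vapply(cts, function(ct) ct$area_km2, 0)
  )
}

#' Trim terminal shelter occupancy from a nighttime subtrack
#'
#' A nighttime period runs sunset to sunrise, but the shark occupies its
#' daytime shelter for the first and last hours of it. The nighttime
#' movement path — the input to patch detection, so that shelter occupancy
#' is not mistaken for a patch — is the subtrack from the first departure
#' beyond `radius_m` of the initial anchor position to the last return
#' within `radius_m` of the final anchor position. Anchors are median
#' positions of the first and last `n_anchor` detections; the default
#' radius is generous relative to a 5-10 m positional error.
#'
#' @param track projected track (`x`, `y`, `timestamp`/`t`).
#' @param radius_m displacement defining departure/return.
#' @param n_anchor detections used for the anchor medians.
#' @return the trimmed track (possibly 0 rows when the shark never left).
#' @export
trim_shelter <- function(track, radius_m = 50, n_anchor = 10) {
  n <- nrow(track)
  if (n < 2 * n_anchor) return(track[0, , drop = FALSE])
  a1 <- c(median(track$x[seq_len(n_anchor)]), median(track$y[seq_len(n_anchor)]))
  a2 <- c(median(track$x[(n - n_anchor + 1):n]), median(track$y[(n - n_anchor + 1):n]))
  d1 <- sqrt((track$x - a1[1])^2 + (track$y - a1[2])^2)
  d2 <- sqrt((track$x - a2[1])^2 + (track$y - a2[2])^2)
  i0 <- which(d1 > radius_m)[1]
  i1 <- tail(which(d2 > radius_m), 1)
  if (is.na(i0) || !length(i1) || i1 < i0) return(track[0, , drop = FALSE])
  track[i0:i1, , drop = FALSE]
}

#' Thin a track to one detection per time bin
#'
#' Keeps the first detection of every `thin_s`-second bin; used to bring
#' second-scale detection streams to relocation scale before FPT,
#' segmentation and bridge estimation.
#'
#' @param track track data.frame (`timestamp` or `t`).
#' @param thin_s bin width in seconds.
#' @return the thinned track.
#' @export
thin_track <- function(track, thin_s) {
  tt <- track_time_s(track)
  keep <- !duplicated(floor(tt / thin_s))
  track[keep, , drop = FALSE]
}

#' Detect ARS patches on a nighttime movement path
#'
#' Runs the full patch-detection chain on a projected nighttime track:
#' thinning, first passage time over the radius sweep (capped by the
#' nighttime core area when given), selection of the ARS scale as the
#' variance-of-log-FPT peak, Lavielle segmentation of the FPT series at
#' that scale (on its largest contiguous defined run; undefined path-end
#' values are excluded, not imputed), and extraction of above-median-FPT
#' segments as patches. Daytime positions must not be included: a shark's
#' daytime resting shelter would otherwise register as a patch.
#'
#' @param track projected nighttime track (`x`, `y`, `timestamp`/`t`).
#' @param thin_s relocation thinning interval (s).
#' @param radii FPT radius sweep (m).
#' @param r50_area_m2 optional nighttime core (50%) area capping the sweep.
#' @param Lmin,Kmax,S Lavielle segmentation controls.
#' @param rule ARS-segment rule passed to [extract_patches()].
#' @return list: `patches` (possibly 0-row), `scale`, `profile`,
#'   `segmentation` (NULL when no signal), `track` (the thinned track),
#'   `low_signal`.
#' @export
detect_patches <- function(track, thin_s = 30, radii = seq(5, 100, by = 5),
                           r50_area_m2 = NULL, Lmin = 10, Kmax = 20,
                           S = 0.75, rule = "median") {
  tr <- thin_track(track, thin_s)
  prof <- fpt(tr, radii)
  sc <- ars_scale(prof, r50_area_m2)
  series <- prof$fpt[, which(prof$radii == sc$radius)]
  # largest contiguous defined run
  def <- is.finite(series)
  r <- rle(def)
  ends <- cumsum(r$lengths); starts <- c(1, head(ends, -1) + 1)
  runs <- which(r$values)
  empty <- function() {
    p <- extract_patches(tr, list(segments = data.frame(first = 1, last = 1)),
                         c(0), sc$radius)[0, ]
    list(patches = p, scale = sc, profile = prof, segmentation = NULL,
         track = tr, low_signal = TRUE)
  }
  if (!length(runs)) return(empty())
  best <- runs[which.max(r$lengths[runs])]
  core_idx <- starts[best]:ends[best]
  if (sc$low_signal || length(core_idx) < 2 * Lmin) return(empty())
  seg <- lavielle_segment(series[core_idx], Lmin = Lmin, Kmax = Kmax, S = S)
  patches <- extract_patches(tr, seg, series[core_idx], sc$radius,
                             series_index = core_idx, rule = rule)
  list(patches = patches, scale = sc, profile = prof, segmentation = seg,
       track = tr, low_signal = sc$low_signal)
}

#' Nighttime subtrack of a diel split
#'
#' @param diel result of [split_diel()].
#' @param complete_only drop partial nights.
#' @return list of `list(period, track)` entries for nights.
#' @export
night_tracks <- function(diel, complete_only = TRUE) {
  keep <- vapply(diel, function(e) {
    e$period$kind == "night" && (!complete_only || !e$period$partial)
  }, TRUE)
  diel[keep]
}
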