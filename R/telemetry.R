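# Telemetry handling: detection CSV IO, the detection-quality filter
# (gain 0 dB, signal 80-105 dB closed interval), diel splitting by computed
# sunrise/sunset, path length, and the cohort inclusion rules that define
# the spatial / accelerometer / paired analysis sets.

TRACK_COLS <- c("shark_id", "timestamp", "lon", "lat", "gain_db", "signal_db")
NOTE_CODES <- c("", "tag_loss", "track_loss", "logger_malfunction")

#' Read and write detection tracks
#'
#' Detection streams are plain CSV with columns `shark_id`, `timestamp`
#' (ISO-8601, UTC), `lon`, `lat`, `gain_db`, `signal_db`. Rows are sorted
#' by timestamp on read (with a warning if they arrived out of order) and
#' exact duplicate timestamps are dropped keeping the first; the number
#' dropped is reported in attribute `n_duplicates`.
#'
#' @param path CSV file path.
#' @return data.frame track; `write_track` returns `path` invisibly.
#' @export
read_track <- function(path) {
  tr <- read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(TRACK_COLS, names(tr))
  if (length(missing)) {
    stop("read_track: missing column(s): ", paste(missing, collapse = ", "))
  }
  ts <- as.POSIXct(tr$timestamp, tz = "UTC",
                   tryFormats = c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS"))
  if (anyNA(ts)) stop("read_track: unparseable timestamp(s)")
  tr$timestamp <- ts
  if (is.unsorted(ts)) {
    warning("read_track: rows out of timestamp order; sorting")
    tr <- tr[order(tr$timestamp), , drop = FALSE]
  }
  dup <- duplicated(tr$timestamp)
  n_dup <- sum(dup)
  if (n_dup) tr <- tr[!dup, , drop = FALSE]
  if (any(abs(tr$lat) > 90)) stop("read_track: latitude outside [-90, 90]")
  rownames(tr) <- NULL
  attr(tr, "n_duplicates") <- n_dup
  tr
}

#' @rdname read_track
#' @param track a track data.frame.
#' @export
write_track <- function(track, path) {
  out <- track
  out$timestamp <- format(track$timestamp, "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  write.csv(out[, TRACK_COLS], path, row.names = FALSE)
  invisible(path)
}

#' Filter detections to highest positional accuracy
#'
#' Retains detections at the reference receiver gain and with signal
#' strength inside a closed interval; with the defaults this keeps only the
#' detections whose positional accuracy is of the order of 5-10 m. The
#' filter is idempotent and never increases the row count.
#'
#' @param track track data.frame.
#' @param gain_db gain to retain (exact match), default 0.
#' @param signal_range closed signal interval in dB, default `c(80, 105)`.
#' @return filtered track with attribute `n_retained` / `n_dropped`.
#' @export
filter_detections <- function(track, gain_db = 0, signal_range = c(80, 105)) {
  keep <- track$gain_db == gain_db &
    track$signal_db >= signal_range[1] & track$signal_db <= signal_range[2]
  out <- track[keep, , drop = FALSE]
  if (nrow(out) == 0) {
    stop("filter_detections: no detections retained; downstream analyses undefined")
  }
  rownames(out) <- NULL
  attr(out, "n_retained") <- nrow(out)
  attr(out, "n_dropped") <- sum(!keep)
  out
}

#' Movement path length
#'
#' Sum of great-circle segment lengths over consecutive detections.
#'
#' @param track track data.frame with >= 2 rows.
#' @return length in km.
#' @export
path_length <- function(track) {
  if (nrow(track) < 2) stop("path_length: need at least 2 detections")
  p <- as.matrix(track[, c("lon", "lat")])
  sum(geosphere::distGeo(p[-nrow(p), , drop = FALSE], p[-1, , drop = FALSE])) / 1000
}

#' Split a track into diel periods
#'
#' Splits a track into alternating daytime (sunrise to sunset) and
#' nighttime (sunset to next sunrise) periods using computed solar times.
#' Day periods are labelled `tagging_day`, `middle_day`, `recovery_day`;
#' nights `night_1`, `night_2`, ... A period cut short by the track bounds
#' is flagged `partial`. For diel-period counting, partial leading/trailing
#' day periods count (tagging and recovery days are inherently partial)
#' but only complete nights do; this yields 2 day + 1 night for 24 h and
#' 38 h tracks and 3 day + 2 night for 48 h tracks.
#'
#' @param track track data.frame.
#' @param lon,lat site coordinates for solar times (default: track medians).
#' @param tz_offset_h local clock offset from UTC (hours), used to pick the
#'   civil dates spanned.
#' @return list of entries, each `list(period = <data.frame>, track = ...)`
#'   where `period` has `kind` ("day"/"night"), `label`, `start`, `end`,
#'   `partial`.
#' @export
split_diel <- function(track, lon = NULL, lat = NULL, tz_offset_h = -7) {
  if (is.null(lon)) lon <- median(track$lon)
  if (is.null(lat)) lat <- median(track$lat)
  t0 <- min(track$timestamp); t1 <- max(track$timestamp)
  dates <- seq(as.Date(t0) - 1, as.Date(t1) + 1, by = 1)
  sol <- lapply(dates, function(d) solar_times(d, lon, lat, tz_offset_h))
  events <- data.frame(
    time = do.call(c, lapply(sol, function(s) c(s$sunrise, s$sunset))),
    type = rep(c("sunrise", "sunset"), length(sol))
  )
  events <- events[order(events$time), ]
  periods <- data.frame(
    start = events$time[-nrow(events)], end = events$time[-1],
    kind = ifelse(events$type[-nrow(events)] == "sunrise", "day", "night")
  )
  keep <- periods$end > t0 & periods$start < t1
  periods <- periods[keep, , drop = FALSE]
  periods$partial <- periods$start < t0 | periods$end > t1
  periods$start <- pmax(periods$start, t0)
  periods$end <- pmin(periods$end, t1)
  nd <- sum(periods$kind == "day"); nn <- sum(periods$kind == "night")
  dlab <- character(nd)
  if (nd > 0) {
    dlab[1] <- "tagging_day"
    if (nd > 1) dlab[nd] <- "recovery_day"
    if (nd > 2) dlab[2:(nd - 1)] <- "middle_day"
  }
  periods$label <- NA_character_
  periods$label[periods$kind == "day"] <- dlab
  periods$label[periods$kind == "night"] <- paste0("night_", seq_len(nn))
  rownames(periods) <- NULL
  lapply(seq_len(nrow(periods)), function(i) {
    p <- periods[i, , drop = FALSE]
    sel <- track$timestamp >= p$start &
      (track$timestamp < p$end |
         (i == nrow(periods) & track$timestamp <= p$end))
    list(period = p, track = track[sel, , drop = FALSE])
  })
}

#' Count diel periods implied by a cohort's track durations
#'
#' Applies the diel-splitting rule per duration class (24 h and 38 h tracks
#' contribute 2 day + 1 complete night; 48 h tracks 3 day + 2 nights) and
#' sums over an analysis set.
#'
#' @param cohort cohort table (see [cohort_table1()]).
#' @param set which analysis set to count over; `"all"` uses every shark.
#' @return named vector `c(day = ..., night = ...)`.
#' @export
diel_period_counts <- function(cohort,
                               set = c("spatial", "accel", "paired", "all")) {
  set <- match.arg(set)
  ids <- if (set == "all") cohort$shark_id else cohort_filter(cohort)[[paste0(set, "_set")]]
  sub <- cohort[cohort$shark_id %in% ids, , drop = FALSE]
  per <- function(d) {
    if (d >= 44) c(3L, 2L) else c(2L, 1L)
  }
  counts <- vapply(sub$duration_h, per, integer(2))
  c(day = sum(counts[1, ]), night = sum(counts[2, ]))
}

#' Cohort inclusion rules
#'
#' Derives the three analysis sets from removal notes: the spatial set
#' excludes tag-loss and track-loss sharks, the accelerometer set excludes
#' tag-loss and logger-malfunction sharks, and the paired set is their
#' intersection.
#'
#' @param cohort cohort table with a `note` column.
#' @return list of character vectors `spatial_set`, `accel_set`,
#'   `paired_set`.
#' @export
cohort_filter <- function(cohort) {
  note <- cohort$note
  note[is.na(note)] <- ""
  bad <- setdiff(unique(note), NOTE_CODES)
  if (length(bad)) {
    stop("cohort_filter: unknown removal-note code(s): ",
         paste(bad, collapse = ", "))
  }
  spatial <- cohort$shark_id[!(note %in% c("tag_loss", "track_loss"))]
  accel <- cohort$shark_id[!(note %in% c("tag_loss", "logger_malfunction"))]
  list(
    spatial_set = spatial,
    accel_set = accel,
    paired_set = intersect(spatial, accel)
  )
}

#' Cohort summary statistics
#'
#' @param cohort cohort table.
#' @return list: `n`, `n_female`, `n_male`, `length_mean_cm`,
#'   `length_sd_cm` (sample SD, n-1 denominator; `NA` for a single shark),
#'   `length_range_cm`.
#' @export
summarize_cohort <- function(cohort) {
  stopifnot(all(c("length_cm", "sex") %in% names(cohort)))
  len <- cohort$length_cm
  list(
    n = nrow(cohort),
    n_female = sum(cohort$sex == "F"),
    n_male = sum(cohort$sex == "M"),
    length_mean_cm = round(mean(len), 2),
    length_sd_cm = if (length(len) > 1) round(sd(len), 2) else NA_real_,
    length_range_cm = range(len)
  )
}
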