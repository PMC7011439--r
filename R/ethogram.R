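# Behavioural ethogram: per-second wavelet frames are grouped by k-means
# into behavioural categories per individual (spectra differ between
# individuals, so clustering is never pooled), resting clusters are the
# low-amplitude ones, and every second receives a binary resting/active
# state.

#' Cluster per-second wavelet frames into behavioural categories
#'
#' k-means with a fixed seed and multiple restarts (best inertia kept) on
#' the per-second amplitude vectors. Clusters whose centre peak amplitude
#' is below `rest_amp_threshold` are labelled resting: motionless seconds
#' produce low-amplitude spectra with no clear cyclic signal. The
#' threshold is configurable because cluster labelling is, in field
#' practice, checked against the cluster summaries.
#'
#' @param frames a [wavelet_spectrum()] object or a numeric matrix of
#'   per-second amplitude vectors.
#' @param k number of behavioural categories (10 stabilises the major
#'   spectral shapes while covering all patterns).
#' @param seed RNG seed for reproducible clustering.
#' @param rest_amp_threshold peak-amplitude threshold (g) below which a
#'   cluster centre is called resting.
#' @param nstart k-means restarts.
#' @param max_fit on streams longer than this many seconds, centres are
#'   fitted on a random subsample of this size and all seconds are then
#'   assigned to their nearest centre (deterministic under `seed`).
#' @return object of class `ethogram_clusters`: `centers`, `labels`,
#'   `resting_ids`, `k`, `time`.
#' @export
cluster_ethogram <- function(frames, k = 10, seed = 7,
                             rest_amp_threshold = 0.1, nstart = 25,
                             max_fit = 10000) {
  amp <- if (inherits(frames, "spectrum_frames")) frames$amp else as.matrix(frames)
  tm <- if (inherits(frames, "spectrum_frames")) frames$time else seq_len(nrow(amp))
  n_distinct <- nrow(unique(amp))
  if (n_distinct < k) {
    stop("cluster_ethogram: only ", n_distinct,
         " distinct frames for k = ", k,
         " (", nrow(amp) - n_distinct, " collapsed)")
  }
  set.seed(seed)
  if (nrow(amp) > max_fit) {
    fit_idx <- sample.int(nrow(amp), max_fit)
    km <- suppressWarnings(
      kmeans(amp[fit_idx, , drop = FALSE], centers = k, nstart = nstart,
             iter.max = 100, algorithm = "MacQueen")
    )
    # assign every second to its nearest centre
    cross <- amp %*% t(km$centers)
    d2 <- outer(rowSums(amp^2), rowSums(km$centers^2), `+`) - 2 * cross
    labels <- max.col(-d2, ties.method = "first")
  } else {
    km <- suppressWarnings(
      kmeans(amp, centers = k, nstart = nstart, iter.max = 100,
             algorithm = "MacQueen")
    )
    labels <- km$cluster
  }
  peak <- apply(km$centers, 1, max)
  resting_ids <- which(peak < rest_amp_threshold)
  if (!length(resting_ids)) {
    warning("cluster_ethogram: no resting cluster below ",
            rest_amp_threshold, " g; individual may be all-active")
  }
  structure(
    list(centers = km$centers, labels = labels,
         resting_ids = as.integer(resting_ids), k = k, time = tm),
    class = "ethogram_clusters"
  )
}

#' Binary resting/active classification per second
#'
#' A second is resting iff its cluster label is one of the resting
#' clusters.
#'
#' @param clusters an [cluster_ethogram()] result.
#' @return data.frame: `time`, `cluster`, `state` ("resting"/"active").
#' @export
classify_activity <- function(clusters) {
  stopifnot(inherits(clusters, "ethogram_clusters"))
  data.frame(
    time = clusters$time,
    cluster = clusters$labels,
    state = ifelse(clusters$labels %in% clusters$resting_ids,
                   "resting", "active")
  )
}

#' Percent time resting per hour of day, by sex
#'
#' @param activity data.frame with columns `id`, `sex`, `time` (POSIXct)
#'   and `state` ("resting"/"active") or logical `resting`.
#' @param tz_offset_h local clock offset from UTC (hours) used to bin
#'   hours of day.
#' @return list: `individual` (per id x hour percent resting), `group`
#'   (per sex x hour mean and SE over individuals).
#' @export
hourly_resting <- function(activity, tz_offset_h = 0) {
  a <- activity
  if (is.null(a$resting)) a$resting <- a$state == "resting"
  a$hour <- floor(((as.numeric(a$time) / 3600 + tz_offset_h) %% 24))
  ind <- aggregate(resting ~ id + sex + hour, data = a,
                   FUN = function(z) 100 * mean(z))
  names(ind)[names(ind) == "resting"] <- "pct_resting"
  se <- function(z) if (length(z) > 1) sd(z) / sqrt(length(z)) else 0
  grp_m <- aggregate(pct_resting ~ sex + hour, data = ind, FUN = mean)
  grp_s <- aggregate(pct_resting ~ sex + hour, data = ind, FUN = se)
  names(grp_m)[3] <- "mean_pct_resting"
  grp_m$se_pct_resting <- grp_s$pct_resting
  list(individual = ind, group = grp_m)
}
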