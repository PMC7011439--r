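# Synthetic night-track generator: a state-switching correlated random walk
# on a local metric plane (shelter rest -> directed transit -> confined
# tortuous patch movement -> shelter), sampled at the detection interval,
# with isotropic Gaussian positional error added to emitted detections.
# Ground truth (true path, per-second behavioural schedule, patch geometry)
# is returned alongside so parameter recovery is testable.

bearing_to <- function(from, to) atan2(to[2] - from[2], to[1] - from[1])

# directed transit: heading re-aimed at the target each step with noise,
# giving a low-tortuosity but not perfectly straight path
transit_leg <- function(pos, target, v, dt, arrive_dist, head_sd = 0.25) {
  d <- sqrt(sum((target - pos)^2))
  max_steps <- ceiling(3 * d / (v * dt)) + 10
  xs <- ys <- numeric(max_steps)
  i <- 0
  while (sqrt(sum((target - pos)^2)) > arrive_dist && i < max_steps) {
    i <- i + 1
    b <- bearing_to(pos, target) + rnorm(1, 0, head_sd)
    pos <- pos + v * dt * c(cos(b), sin(b))
    xs[i] <- pos[1]; ys[i] <- pos[2]
  }
  list(xy = cbind(x = xs[seq_len(i)], y = ys[seq_len(i)]), pos = pos)
}

# high-tortuosity confined walk inside a patch circle
patch_walk <- function(pos, center, R, n_steps, v, dt) {
  xs <- ys <- numeric(n_steps)
  heading <- runif(1, 0, 2 * pi)
  for (i in seq_len(n_steps)) {
    heading <- heading + rnorm(1, 0, 0.8)
    cand <- pos + v * dt * c(cos(heading), sin(heading))
    if (sqrt(sum((cand - center)^2)) > 0.85 * R) {
      heading <- bearing_to(pos, center) + rnorm(1, 0, 0.4)
      cand <- pos + v * dt * c(cos(heading), sin(heading))
    }
    pos <- cand
    xs[i] <- pos[1]; ys[i] <- pos[2]
  }
  list(xy = cbind(x = xs, y = ys), pos = pos)
}

# near-stationary jitter (shelter or in-patch resting)
rest_walk <- function(pos, n_steps, sd = 0.25) {
  xy <- cbind(
    x = pos[1] + rnorm(n_steps, 0, sd),
    y = pos[2] + rnorm(n_steps, 0, sd)
  )
  list(xy = xy, pos = pos)
}

# anchored patch use: rest at an anchor, occasionally swim to a new anchor
# inside the patch (regime "burst"); regime "rest" stays at one anchor near
# the patch centre throughout. Returns per-sample positions and states
# ("patch_rest" while anchored, "patch_moderate" while repositioning).
patch_anchored_leg <- function(pos, center, R, n_steps, dt,
                               relocate = TRUE, v = 0.2,
                               dwell_mean_s = 240) {
  xs <- ys <- numeric(n_steps)
  st <- character(n_steps)
  draw_anchor <- function(rmax) {
    b <- runif(1, 0, 2 * pi)
    center + runif(1, 0, rmax) * c(cos(b), sin(b))
  }
  anchor <- if (relocate) draw_anchor(0.6 * R) else
    draw_anchor(min(0.3 * R, 15))
  i <- 0
  # initial swim from the entry point to the first anchor
  mode <- "move"
  while (i < n_steps) {
    if (mode == "move") {
      d <- sqrt(sum((anchor - pos)^2))
      hop <- max(1L, ceiling(d / (v * dt)))
      for (h in seq_len(hop)) {
        if (i >= n_steps) break
        i <- i + 1
        b <- bearing_to(pos, anchor) + rnorm(1, 0, 0.2)
        pos <- pos + min(v * dt, sqrt(sum((anchor - pos)^2))) * c(cos(b), sin(b))
        xs[i] <- pos[1]; ys[i] <- pos[2]
        st[i] <- "patch_moderate"
      }
      mode <- "dwell"
    } else {
      dwell <- max(3L, ceiling(stats::rexp(1, 1 / dwell_mean_s) / dt))
      for (h in seq_len(dwell)) {
        if (i >= n_steps) break
        i <- i + 1
        xs[i] <- anchor[1] + rnorm(1, 0, 0.25)
        ys[i] <- anchor[2] + rnorm(1, 0, 0.25)
        st[i] <- "patch_rest"
      }
      pos <- anchor
      if (relocate) {
        anchor <- draw_anchor(0.6 * R)
        mode <- "move"
      }
    }
  }
  list(xy = cbind(x = xs, y = ys), pos = pos, state = st)
}

# per-second state vector for a burst-regime patch: resting baseline with
# embedded 1-5 s burst runs
burst_states <- function(n_sec, p_burst) {
  st <- rep("patch_rest", n_sec)
  i <- 1
  while (i <= n_sec) {
    if (runif(1) < p_burst) {
      len <- sample(1:5, 1)
      st[i:min(n_sec, i + len - 1)] <- "patch_burst"
      i <- i + len + 2
    } else {
      i <- i + 1
    }
  }
  st
}

#' Simulate one (or more) nights of active tracking with known truth
#'
#' Generates a detection stream mimicking continuous active acoustic
#' tracking of a nocturnal demersal shark: stationary daytime shelter rest,
#' departure a configurable offset after sunset, directed transit between
#' reefs, confined high-tortuosity movement inside each true patch circle,
#' and return to a (new) daytime shelter before sunrise. Detections carry
#' isotropic Gaussian positional noise and receiver-quality fields; a small
#' fraction of detections are emitted at lower quality so the
#' detection-quality filter has something to remove.
#'
#' @param config a [sim_config()].
#' @return list with `track` (data.frame: `shark_id`, `timestamp` (UTC),
#'   `lon`, `lat`, `gain_db`, `signal_db`) and `truth` (list: `path` =
#'   true per-sample positions and states, `schedule` = per-second states,
#'   `patches` = realised patch centres/radii/entry/exit/regime,
#'   `shelters`, `origin`, `night_windows`).
#' @export
simulate_night_track <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  set.seed(cfg$seed)
  dt <- cfg$sample_interval_s
  n_samp <- as.integer(round(cfg$duration_h * 3600 / dt))
  t0 <- as.POSIXct(as.numeric(as.Date(cfg$date)) * 86400,
                   origin = "1970-01-01", tz = "UTC") +
    (cfg$start_local_h - cfg$tz_offset_h) * 3600
  times <- t0 + (seq_len(n_samp) - 1) * dt
  t_end <- times[n_samp] + dt

  # night windows overlapping the track
  dates <- seq(as.Date(cfg$date) - 1, as.Date(cfg$date) + ceiling(cfg$duration_h / 24) + 1, by = 1)
  sol <- lapply(dates, function(d) {
    solar_times(d, cfg$site_origin[1], cfg$site_origin[2], cfg$tz_offset_h)
  })
  nights <- do.call(rbind, lapply(seq_len(length(sol) - 1), function(i) {
    data.frame(sunset = sol[[i]]$sunset, sunrise = sol[[i + 1]]$sunrise)
  }))
  nights <- nights[nights$sunset < t_end & nights$sunrise > t0, , drop = FALSE]
  nights <- nights[nights$sunset >= t0, , drop = FALSE] # full nights only

  shelter <- c(runif(1, -80, 80), runif(1, -80, 80))
  pos <- shelter

  leg_xy <- list(); leg_state <- list()
  patches <- list(); shelters <- list()
  shelter_from <- t0
  cursor <- 0L # samples generated so far

  add_leg <- function(xy, state_s) {
    leg_xy[[length(leg_xy) + 1]] <<- xy
    leg_state[[length(leg_state) + 1]] <<- state_s
    cursor <<- cursor + nrow(xy)
  }
  samp_time <- function(i) times[min(i, n_samp)]

  for (ni in seq_len(nrow(nights))) {
    night <- nights[ni, ]
    night_len <- as.numeric(night$sunrise) - as.numeric(night$sunset)
    depart <- as.numeric(night$sunset) +
      rtnorm1(cfg$depart_after_sunset_h, cfg$depart_sd_h, 0.5, 5.5) * 3600
    deadline <- as.numeric(night$sunrise) -
      rtnorm1(cfg$leave_before_sunrise_h, cfg$leave_sd_h, 0.5, 5.5) * 3600
    if (deadline - depart < 5400) {
      depart <- as.numeric(night$sunset) + 0.2 * night_len
      deadline <- as.numeric(night$sunrise) - 0.2 * night_len
    }

    # shelter rest until departure
    n_rest <- max(0L, floor((depart - as.numeric(samp_time(cursor + 1))) / dt))
    n_rest <- min(n_rest, n_samp - cursor)
    if (n_rest > 0) {
      lg <- rest_walk(shelter, n_rest)
      add_leg(lg$xy, rep("shelter_rest", n_rest * dt))
    }
    if (cursor >= n_samp) break
    shelters[[length(shelters) + 1]] <- data.frame(
      x = shelter[1], y = shelter[2], from = shelter_from,
      to = samp_time(cursor)
    )

    k <- if (is.null(cfg$n_patches)) {
      sample(1:3, 1, prob = c(0.79, 0.14, 0.07))
    } else cfg$n_patches
    radii <- if (is.null(cfg$patch_radius_m)) draw_patch_radius(max(k, 1)) else
      rep_len(cfg$patch_radius_m, max(k, 1))
    regimes <- if (is.null(cfg$patch_regime)) draw_regimes(max(k, 1)) else
      rep_len(cfg$patch_regime, max(k, 1))
    res_s <- pmin(pmax(rlnorm(max(k, 1), log(cfg$residence_h), 0.55), 0.3), 5) * 3600
    dists <- vapply(seq_len(max(k, 1)), function(j) rtnorm1(450, 300, 150, 1200), 0)

    # feasibility: shrink residences (then distances) to fit the window
    avail <- deadline - depart
    travel_est <- sum(1.3 * dists / cfg$transit_speed) + 1.3 * 450 / cfg$transit_speed
    if (k > 0 && travel_est + sum(res_s) > avail) {
      res_s <- res_s * max(0.25, (avail - travel_est) / sum(res_s))
      if (travel_est > 0.8 * avail) {
        f <- 0.8 * avail / travel_est
        dists <- dists * f
        travel_est <- travel_est * f
        res_s <- pmax(res_s, 900)
      }
    }

    # patch legs
    pos <- shelter
    if (k > 0) {
      for (j in seq_len(k)) {
        if (cursor >= n_samp) break
        b <- runif(1, 0, 2 * pi)
        center <- pos + dists[j] * c(cos(b), sin(b))
        lg <- transit_leg(pos, center, cfg$transit_speed, dt,
                          arrive_dist = 0.7 * radii[j])
        nt <- min(nrow(lg$xy), n_samp - cursor)
        add_leg(lg$xy[seq_len(nt), , drop = FALSE], rep("transit", nt * dt))
        pos <- lg$pos
        if (cursor >= n_samp) break
        # stop early if the deadline leaves no room to get home
        t_now <- as.numeric(samp_time(cursor))
        room <- deadline - t_now - 1.3 * 450 / cfg$transit_speed
        if (room < 900) break
        stay <- min(res_s[j], room)
        n_stay <- max(1L, min(floor(stay / dt), n_samp - cursor))
        entry <- samp_time(cursor + 1)
        if (regimes[j] == "moderate") {
          lg <- patch_walk(pos, center, radii[j], n_stay, cfg$patch_speed, dt)
          st <- rep("patch_moderate", n_stay * dt)
        } else {
          lg <- patch_anchored_leg(pos, center, radii[j], n_stay, dt,
                                   relocate = regimes[j] == "burst")
          st <- rep(lg$state, each = dt)
          if (regimes[j] == "burst") {
            rest_sec <- st == "patch_rest"
            st[rest_sec] <- burst_states(sum(rest_sec), cfg$burst_prob_per_s)
          }
        }
        add_leg(lg$xy, st)
        pos <- lg$pos
        patches[[length(patches) + 1]] <- data.frame(
          night = ni, patch_id = sprintf("N%d_P%d", ni, j),
          cx = center[1], cy = center[2], radius_m = radii[j],
          regime = regimes[j], entry = entry, exit = samp_time(cursor)
        )
      }
    } else {
      # explicit zero-patch night: out-and-back transit only
      b <- runif(1, 0, 2 * pi)
      far <- pos + rtnorm1(800, 200, 400, 1200) * c(cos(b), sin(b))
      lg <- transit_leg(pos, far, cfg$transit_speed, dt, arrive_dist = 10)
      nt <- min(nrow(lg$xy), n_samp - cursor)
      add_leg(lg$xy[seq_len(nt), , drop = FALSE], rep("transit", nt * dt))
      pos <- lg$pos
    }

    # return to a new morning shelter
    if (cursor < n_samp) {
      b <- runif(1, 0, 2 * pi)
      new_shelter <- pos + rtnorm1(400, 200, 150, 800) * c(cos(b), sin(b))
      lg <- transit_leg(pos, new_shelter, cfg$transit_speed, dt, arrive_dist = 8)
      nt <- min(nrow(lg$xy), n_samp - cursor)
      add_leg(lg$xy[seq_len(nt), , drop = FALSE], rep("transit", nt * dt))
      pos <- lg$pos
      shelter <- pos
      shelter_from <- samp_time(cursor)
    }
  }

  # trailing shelter rest to the end of the track
  if (cursor < n_samp) {
    n_rest <- n_samp - cursor
    lg <- rest_walk(shelter, n_rest)
    add_leg(lg$xy, rep("shelter_rest", n_rest * dt))
    shelters[[length(shelters) + 1]] <- data.frame(
      x = shelter[1], y = shelter[2], from = shelter_from, to = t_end
    )
  }

  xy <- do.call(rbind, leg_xy)
  state_samp <- unlist(lapply(seq_along(leg_xy), function(i) {
    s <- leg_state[[i]]
    s[seq(1, length(s), by = dt)][seq_len(nrow(leg_xy[[i]]))]
  }))
  stopifnot(nrow(xy) == n_samp)

  path <- data.frame(time = times, x = xy[, 1], y = xy[, 2],
                     state = state_samp)
  sched_state <- unlist(leg_state)
  sched_state <- sched_state[seq_len(cfg$duration_h * 3600)]
  schedule <- data.frame(
    time = t0 + seq_len(length(sched_state)) - 1,
    state = sched_state
  )

  # emitted detections: positional noise + receiver-quality fields
  err <- matrix(rnorm(2 * n_samp, 0, cfg$detection_error_sd_m), ncol = 2)
  ll <- xy_to_lonlat(xy[, 1] + err[, 1], xy[, 2] + err[, 2], cfg$site_origin)
  good <- runif(n_samp) < 0.92
  gain <- ifelse(good, 0, sample(c(6, 12), n_samp, replace = TRUE))
  signal <- ifelse(good, runif(n_samp, 80, 105), runif(n_samp, 60, 100))
  track <- data.frame(
    shark_id = cfg$shark_id, timestamp = times,
    lon = ll$lon, lat = ll$lat, gain_db = gain, signal_db = signal
  )

  patches_df <- if (length(patches)) do.call(rbind, patches) else
    data.frame(night = integer(), patch_id = character(), cx = numeric(),
               cy = numeric(), radius_m = numeric(), regime = character(),
               entry = as.POSIXct(character(), tz = "UTC"),
               exit = as.POSIXct(character(), tz = "UTC"))
  if (nrow(patches_df)) {
    pll <- xy_to_lonlat(patches_df$cx, patches_df$cy, cfg$site_origin)
    patches_df$lon <- pll$lon; patches_df$lat <- pll$lat
  }
  truth <- list(
    path = path, schedule = schedule, patches = patches_df,
    shelters = do.call(rbind, shelters), origin = cfg$site_origin,
    night_windows = nights, config = cfg
  )
  list(track = track, truth = truth)
}

#' Write simulation ground truth as JSON
#'
#' @param truth the `truth` element of [simulate_night_track()].
#' @param path output file.
#' @export
write_truth_json <- function(truth, path) {
  sched <- rle(truth$schedule$state)
  out <- list(
    origin = truth$origin,
    patches = truth$patches,
    shelters = truth$shelters,
    schedule_rle = data.frame(state = sched$values, length = sched$lengths,
                              stringsAsFactors = FALSE)
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = 8, POSIXt = "ISO8601")
  invisible(path)
}
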