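mk_activity <- function(n_sec, state = "resting", odba = 0.05,
                        depth = 10, temp = 18,
                        t0 = as.POSIXct("2017-08-10 04:00:00", tz = "UTC")) {
  data.frame(time = t0 + 0:(n_sec - 1),
             state = rep_len(state, n_sec),
             odba_g = rep_len(odba, n_sec),
             depth_m = rep_len(depth, n_sec),
             temp_c = rep_len(temp, n_sec))
}

mk_patch <- function(t0, dur_s, id = "p1") {
  data.frame(patch_id = id, entry = t0, exit = t0 + dur_s)
}

test_that("patch-activity join aggregates states, ODBA and coverage", {
  t0 <- as.POSIXct("2017-08-10 04:00:00", tz = "UTC")
  act <- mk_activity(3600)
  pa <- join_patch_activity(mk_patch(t0, 1800), act)
  expect_equal(pa$pct_resting, 100)
  expect_equal(pa$coverage, 1, tolerance = 1e-3)

  act2 <- act
  act2$state <- rep(c("resting", "active"), 1800)
  pa2 <- join_patch_activity(mk_patch(t0, 1800), act2)
  expect_equal(pa2$pct_resting, 50, tolerance = 0.1)

  # per-patch mean ODBA equals direct recomputation
  set.seed(40)
  act3 <- act
  act3$odba_g <- runif(3600, 0, 2)
  pa3 <- join_patch_activity(mk_patch(t0 + 600, 1200), act3)
  sel <- act3$time >= t0 + 600 & act3$time <= t0 + 1800
  expect_equal(pa3$odba_mean_g, mean(act3$odba_g[sel]))

  # coverage gap flags the patch
  gap <- act[-(100:500), ]
  pa4 <- join_patch_activity(mk_patch(t0, 1800), gap)
  expect_true(pa4$coverage_gap)
  expect_equal(classify_patch(pa4)$class, "excluded")
})

test_that("patch classification rules: resting, moderate, episodic burst", {
  t0 <- as.POSIXct("2017-08-10 04:00:00", tz = "UTC")
  # motionless, low ODBA, flat depth -> resting and excluded from stats
  rest <- join_patch_activity(mk_patch(t0, 1800),
                              mk_activity(1801, "resting", 0.1, depth = 10.2))
  cr <- classify_patch(rest)
  expect_equal(cr$class, "resting")
  expect_true(cr$excluded_from_stats)

  # continuous ~1 g, no rest -> moderate
  mod <- join_patch_activity(mk_patch(t0, 1800),
                             mk_activity(1801, "active", 1.0))
  expect_equal(classify_patch(mod)$class, "moderate_active")

  # 60% resting with three 2-s runs at 2.5 g -> episodic burst
  a <- mk_activity(1801, "resting", 0.05)
  a$state[1:720] <- "active"
  for (s in c(300, 800, 1300)) a$odba_g[s:(s + 1)] <- 2.5
  eb <- join_patch_activity(mk_patch(t0, 1800), a)
  expect_equal(eb$burst_count, 3)
  expect_equal(classify_patch(eb)$class, "episodic_burst")

  # depth change disqualifies resting even when motionless
  deep <- mk_activity(1801, "resting", 0.1)
  deep$depth_m <- seq(10, 13, length.out = 1801)
  expect_equal(classify_patch(join_patch_activity(mk_patch(t0, 1800), deep))$class,
               "moderate_active")
})

test_that("raising burst amplitude never flips episodic to moderate", {
  t0 <- as.POSIXct("2017-08-10 04:00:00", tz = "UTC")
  for (amp in c(2, 2.5, 3, 5, 8)) {
    a <- mk_activity(1801, "resting", 0.05)
    a$state[1:600] <- "active"
    for (s in c(300, 900, 1500)) a$odba_g[s:(s + 2)] <- amp
    cls <- classify_patch(join_patch_activity(mk_patch(t0, 1800), a))$class
    expect_equal(cls, "episodic_burst")
  }
})

test_that("patch summaries: empty tables, class conservation, arrival offsets", {
  empty <- patch_summary(data.frame(patch_id = character(),
                                    class = character(),
                                    residence_min = numeric()))
  expect_equal(empty$n_active, 0)

  t0 <- as.POSIXct("2017-08-10 04:00:00", tz = "UTC")
  pt <- data.frame(
    patch_id = c("a", "b", "c", "d"),
    class = c("resting", "episodic_burst", "moderate_active", "excluded"),
    residence_min = c(60, 90, 120, 30),
    area_m2 = c(100, 500, 900, 50),
    night = c(1, 1, 2, 2),
    entry = t0 + c(0, 7200, 0, 3600) ,
    exit = t0 + c(3600, 10800, 3600, 7200),
    sunset = rep(t0 - 3 * 3600, 4),
    sunrise = rep(t0 + 7 * 3600, 4)
  )
  s <- patch_summary(pt)
  expect_equal(s$n_active, 2)
  expect_equal(sum(s$by_class), 4)
  expect_equal(unname(s$arrival_after_sunset_h["mean"]), 3) # first patch per night
})

test_that("planted arrival offsets are recovered from generated nights", {
  offs <- c()
  for (s in 1:10) {
    cfg <- sim_config(seed = 1100 + s, depart_sd_h = 2.2)
    sim <- simulate_night_track(cfg)
    if (!nrow(sim$truth$patches)) next
    nw <- sim$truth$night_windows[1, ]
    offs <- c(offs, (as.numeric(sim$truth$patches$entry[1]) -
                       as.numeric(nw$sunset)) / 3600)
  }
  # planted mean departure 3.4 h plus travel time to the first patch
  expect_gt(length(offs), 5)
  expect_lt(abs(mean(offs) - 3.4), 1.5)
})

test_that("core overlap: containment, disjointness, Monte-Carlo agreement", {
  sq <- function(x0, y0, s) cbind(x = c(x0, x0 + s, x0 + s, x0),
                                  y = c(y0, y0, y0 + s, y0 + s))
  # fake core contour as a polygon region list
  core_poly <- sq(-50, -50, 300)
  inside <- sq(0, 0, 100)
  ov <- core_overlap(list(inside), list(core_poly))
  expect_equal(ov$overlap_km2, ov$patch_area_km2, tolerance = 1e-9)
  expect_equal(ov$overlap_km2 * 1e6, 100 * 100, tolerance = 200)

  far <- sq(1000, 1000, 100)
  expect_equal(core_overlap(list(far), list(core_poly))$overlap_km2, 0)

  set.seed(41)
  pa <- make_convex_poly(0, 0, 120)
  pb <- make_convex_poly(40, -30, 100)
  ov2 <- core_overlap(list(pa), list(pb))
  bbox <- c(min(pa[, 1], pb[, 1]), max(pa[, 1], pb[, 1]),
            min(pa[, 2], pb[, 2]), max(pa[, 2], pb[, 2]))
  mc <- oracle_mc_overlap(function(x, y) pip(x, y, pa),
                          function(x, y) pip(x, y, pb), bbox)
  expect_lt(abs(ov2$overlap_km2 * 1e6 - mc), 0.015 * mc)
})
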