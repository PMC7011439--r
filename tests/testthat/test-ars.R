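test_that("FPT is exact on straight lines and undefined at path ends", {
  tr <- straight_track(len = 400, step = 2, v = 1)
  pr <- fpt(tr, radii = c(10, 25, 50))
  mid <- 101
  expect_equal(pr$fpt[mid, ], c(20, 50, 100))
  expect_true(all(is.na(pr$fpt[1, ])))
  expect_true(all(is.na(pr$fpt[nrow(tr), ])))
  expect_error(fpt(tr, radii = c(0.5, 10)), "radii")
})

test_that("FPT is non-decreasing in radius where defined", {
  set.seed(20)
  tr <- data.frame(x = cumsum(rnorm(150, 0, 8)), y = cumsum(rnorm(150, 0, 8)),
                   t = (1:150) * 30)
  pr <- fpt(tr, radii = c(5, 10, 20, 40, 80))
  for (i in seq_len(nrow(tr))) {
    row <- pr$fpt[i, ]
    row <- row[is.finite(row)]
    if (length(row) > 1) expect_true(all(diff(row) >= -1e-9))
  }
})

test_that("FPT agrees with a densified brute-force crossing search", {
  set.seed(22)
  for (rep in 1:6) {
    n <- sample(60:120, 1)
    tr <- data.frame(x = cumsum(rnorm(n, 0, 3)), y = cumsum(rnorm(n, 0, 3)),
                     t = (1:n) * 2)
    radii <- c(6, 12, 24)
    pr <- fpt(tr, radii)
    for (i in sample(5:(n - 5), 4)) {
      for (ri in seq_along(radii)) {
        br <- oracle_fpt(tr$x, tr$y, tr$t, i, radii[ri])
        if (is.na(br)) {
          expect_true(is.na(pr$fpt[i, ri]))
        } else {
          expect_lt(abs(pr$fpt[i, ri] - br), 2 + 1e-9) # one sample interval
        }
      }
    }
  }
})

test_that("ARS scale selection: cap formula, recovery, low-signal flag", {
  # cap: core area pi * 40^2 limits the sweep to 40 m
  tr <- straight_track(len = 2000, step = 10, v = 0.5)
  pr <- fpt(tr, radii = seq(5, 100, by = 5))
  sc <- ars_scale(pr, r50_area_m2 = pi * 40^2)
  expect_lte(sc$radius, 40)
  expect_true(sc$low_signal) # pure transit: flat variance of log FPT

  # recovery: with the core-area cap (integral to the method — the variance
  # of log FPT keeps growing past the patch scale on noisy tracks), planted
  # 30 m patches select a scale commensurate with the patch radius
  hits <- 0
  for (s in 1:8) {
    cfg <- sim_config(seed = 700 + s, n_patches = 1, patch_radius_m = 30,
                      patch_regime = "moderate")
    sim <- simulate_night_track(cfg)
    tr2 <- track_xy(filter_detections(sim$track), origin = cfg$site_origin)
    nw <- sim$truth$night_windows[1, ]
    mv <- trim_shelter(tr2[tr2$timestamp >= nw$sunset & tr2$timestamp < nw$sunrise, ])
    asp <- activity_space(mv, isopleths = 0.5, thin_s = 60, cell_size_m = 10)
    pr2 <- fpt(thin_track(mv, 30), radii = seq(5, 60, by = 5))
    sc2 <- ars_scale(pr2, r50_area_m2 = asp$areas_km2[[1]] * 1e6)
    if (sc2$radius >= 10 && sc2$radius <= 45) hits <- hits + 1
  }
  expect_gte(hits, 6)
})

test_that("Lavielle segmentation: step series, constant series, contrast properties", {
  x <- c(rep(0, 25), rep(5, 25))
  sg <- lavielle_segment(x, Lmin = 5, Kmax = 10)
  expect_equal(sg$K_opt, 2L)
  expect_equal(sg$changepoints, 25)

  expect_equal(lavielle_segment(rep(3, 60), Lmin = 5, Kmax = 10)$K_opt, 1L)

  set.seed(25)
  y <- rnorm(120)
  sg2 <- lavielle_segment(y, Lmin = 8, Kmax = 12)
  expect_true(all(diff(sg2$J) <= 1e-9))               # J non-increasing in K
  expect_true(all(with(sg2$segments, last - first + 1) >= 8)) # Lmin respected
  expect_error(lavielle_segment(c(1, NA, 3, rep(0, 30)), Lmin = 3), "NA")
})

test_that("Lavielle DP equals exhaustive partition enumeration", {
  set.seed(26)
  for (rep in 1:25) {
    n <- sample(15:30, 1)
    x <- rnorm(n) + rep(c(0, 3), each = ceiling(n / 2))[1:n]
    Lmin <- 3
    sg <- lavielle_segment(x, Lmin = Lmin, Kmax = 4)
    for (K in 1:4) {
      if (n >= K * Lmin) {
        expect_equal(sg$J[K], oracle_partition_sse(x, K, Lmin),
                     tolerance = 1e-8)
      }
    }
  }
})

test_that("patch extraction: hull bound, degenerate members, recovery", {
  # all member points within 50 m of the centroid bound the MCP area
  set.seed(27)
  th <- runif(200, 0, 2 * pi); rr <- sqrt(runif(200)) * 50
  tr <- data.frame(x = rr * cos(th), y = rr * sin(th), t = (1:200) * 30)
  seg <- list(segments = data.frame(first = 1, last = 200))
  ser <- exp(seq(log(10), log(1000), length.out = 200)) # mean > median
  p <- extract_patches(tr, seg, ser, 25, rule = "median")
  expect_equal(nrow(p), 1)
  expect_lte(p$area_m2, pi * 50^2)

  # collinear members: degenerate flag, zero area
  tr2 <- data.frame(x = (1:40) * 0.5, y = 0, t = (1:40) * 30)
  p2 <- extract_patches(tr2, list(segments = data.frame(first = 1, last = 40)),
                        exp(seq(log(10), log(1000), length.out = 40)), 25,
                        rule = "median", merge_dist_m = 0,
                        min_residence_min = 0)
  expect_true(p2$degenerate)
  expect_equal(p2$area_m2, 0)

  # single planted patch: count, centroid, residence (a few seeds here; the
  # 20-night experiment lives in the acceptance suite)
  for (s in 1:4) {
    cfg <- sim_config(seed = 800 + s, n_patches = 1, patch_radius_m = 30,
                      patch_regime = "moderate")
    sim <- simulate_night_track(cfg)
    tr3 <- track_xy(filter_detections(sim$track), origin = cfg$site_origin)
    nw <- sim$truth$night_windows[1, ]
    mv <- trim_shelter(tr3[tr3$timestamp >= nw$sunset & tr3$timestamp < nw$sunrise, ])
    asp <- activity_space(mv, isopleths = 0.5, thin_s = 60, cell_size_m = 10)
    dp <- detect_patches(mv, r50_area_m2 = asp$areas_km2[[1]] * 1e6)
    expect_equal(nrow(dp$patches), 1)
    truth <- sim$truth$patches
    expect_lt(sqrt((dp$patches$cx - truth$cx)^2 + (dp$patches$cy - truth$cy)^2), 25)
    res_t <- as.numeric(truth$exit) - as.numeric(truth$entry)
    res_f <- as.numeric(dp$patches$exit) - as.numeric(dp$patches$entry)
    expect_lt(abs(res_f - res_t) / res_t, 0.2)
  }
})

test_that("nighttime-only analysis never places a patch in a daytime shelter", {
  for (s in 1:4) {
    cfg <- sim_config(seed = 900 + s)
    sim <- simulate_night_track(cfg)
    tr <- track_xy(filter_detections(sim$track), origin = cfg$site_origin)
    nw <- sim$truth$night_windows[1, ]
    mv <- trim_shelter(tr[tr$timestamp >= nw$sunset & tr$timestamp < nw$sunrise, ])
    asp <- activity_space(mv, isopleths = 0.5, thin_s = 60, cell_size_m = 10)
    dp <- detect_patches(mv, r50_area_m2 = asp$areas_km2[[1]] * 1e6)
    sh <- sim$truth$shelters
    for (j in seq_len(nrow(dp$patches))) {
      d <- sqrt((sh$x - dp$patches$cx[j])^2 + (sh$y - dp$patches$cy[j])^2)
      expect_gt(min(d), 50)
    }
  }
})

test_that("patch distances are exact and match great-circle computation", {
  patches <- data.frame(patch_id = c("p1", "p2"),
                        cx = c(300, 800), cy = c(0, 0))
  d <- patch_distances(patches, shelter_from = c(0, 0), shelter_to = c(800, 600))
  expect_equal(d$distance_m, c(300, 500, 600))
  # coincident shelter and patch centroid
  d0 <- patch_distances(patches[1, ], shelter_from = c(300, 0))
  expect_equal(d0$distance_m, 0)
  # planar vs spherical great-circle within 0.1% at site scale
  org <- c(-118.49, 33.445)
  ll1 <- xy_to_lonlat(0, 0, org); ll2 <- xy_to_lonlat(300, 0, org)
  gc <- geosphere::distHaversine(as.matrix(ll1), as.matrix(ll2))
  expect_lt(abs(gc - 300) / 300, 0.001)
})
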