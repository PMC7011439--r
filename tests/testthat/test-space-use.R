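test_that("sig1 optimisation matches a brute-force grid search", {
  set.seed(8)
  n <- 201; dt <- 10; s1 <- 0.6; s2 <- 1
  tr <- data.frame(
    x = cumsum(rnorm(n, 0, s1 * sqrt(dt))) + rnorm(n, 0, s2),
    y = cumsum(rnorm(n, 0, s1 * sqrt(dt))) + rnorm(n, 0, s2),
    t = (1:n) * dt
  )
  est <- estimate_sig1(tr, sig2 = s2)
  grid <- seq(1e-4, 10, length.out = 1000)
  tt <- tr$t; x <- tr$x; y <- tr$y
  mid <- seq(2, n - 1, by = 2); i0 <- mid - 1; i1 <- mid + 1
  Tm <- tt[i1] - tt[i0]; a <- (tt[mid] - tt[i0]) / Tm
  mux <- (1 - a) * x[i0] + a * x[i1]; muy <- (1 - a) * y[i0] + a * y[i1]
  ll <- vapply(grid, function(s) {
    v <- Tm * a * (1 - a) * s^2 + ((1 - a)^2 + a^2) * s2^2
    sum(dnorm(x[mid], mux, sqrt(v), log = TRUE) +
          dnorm(y[mid], muy, sqrt(v), log = TRUE))
  }, 0)
  expect_lt(abs(est - grid[which.max(ll)]), diff(grid[1:2]) * 1.01)
})

test_that("sig1 is recovered on pure Brownian motion and collapses on straight lines", {
  set.seed(9)
  n <- 501; dt <- 10; s1 <- 0.5; s2 <- 0.1
  tr <- data.frame(
    x = cumsum(rnorm(n, 0, s1 * sqrt(dt))) + rnorm(n, 0, s2),
    y = cumsum(rnorm(n, 0, s1 * sqrt(dt))) + rnorm(n, 0, s2),
    t = (1:n) * dt
  )
  expect_lt(abs(estimate_sig1(tr, sig2 = s2) - s1) / s1, 0.15)

  line <- data.frame(x = (1:101) * 5, y = 0, t = (1:101) * 10)
  expect_lt(estimate_sig1(line, sig2 = 0.01), 0.01)
})

test_that("bridge UD mass is 1 and the single-pair midpoint matches the closed form", {
  tr <- data.frame(x = c(0, 100), y = c(0, 0), t = c(0, 600))
  s1 <- 0.8; s2 <- 5
  ud <- bbkud(tr, s1, s2, cell_size_m = 2, alpha_steps = 1) # midpoint only
  expect_equal(sum(ud$z), 1, tolerance = 1e-6)
  v <- 600 / 4 * s1^2 + s2^2 / 2
  ref <- dnorm(ud$x, 50, sqrt(v)) %o% dnorm(ud$y, 0, sqrt(v))
  ref <- ref / sum(ref)
  expect_lt(max(abs(ud$z - ref)), 1e-4 * max(ref))

  # coincident points: mass concentrates within ~3 sig2 of the point
  tr2 <- data.frame(x = c(10, 10), y = c(-5, -5), t = c(0, 60))
  ud2 <- bbkud(tr2, 0.5, 5, cell_size_m = 1)
  cells <- expand.grid(x = ud2$x, y = ud2$y)
  d <- sqrt((cells$x - 10)^2 + (cells$y + 5)^2)
  expect_gte(sum(ud2$z[d <= 3 * 5 * sqrt(2)]), 0.99)
})

test_that("isopleth contours nest, cover the support at 1.0, and match the Gaussian limit", {
  sig <- 30; cell <- 3
  gx <- seq(-160, 160, by = cell); gy <- gx
  z <- dnorm(gx, 0, sig) %o% dnorm(gy, 0, sig); z <- z / sum(z)
  ud <- structure(list(x = gx, y = gy, z = z, cell_size_m = cell),
                  class = "bbkud")
  c95 <- ud_contour(ud, 0.95); c50 <- ud_contour(ud, 0.50)
  expect_lte(c50$area_km2, c95$area_km2)
  # isopleth 1.0 covers the entire support (uniform compact-support UD)
  zu <- matrix(0, 40, 40); zu[11:30, 11:30] <- 1 / 400
  udu <- structure(list(x = 1:40, y = 1:40, z = zu, cell_size_m = 1),
                   class = "bbkud")
  expect_equal(ud_contour(udu, 1.0)$area_km2, 400 / 1e6)
  expect_lt(abs(c95$area_km2 * 1e6 / (pi * sig^2 * qchisq(0.95, 2)) - 1), 0.05)
})

test_that("contours shift with the data (translation equivariance)", {
  set.seed(12)
  tr <- data.frame(x = cumsum(rnorm(60, 0, 10)), y = cumsum(rnorm(60, 0, 10)),
                   t = (1:60) * 30)
  ud1 <- bbkud(tr, 0.7, 5, cell_size_m = 5)
  tr2 <- tr; tr2$x <- tr$x + 500; tr2$y <- tr$y - 250
  ud2 <- bbkud(tr2, 0.7, 5, cell_size_m = 5)
  c1 <- ud_contour(ud1, 0.95); c2 <- ud_contour(ud2, 0.95)
  expect_equal(c1$area_km2, c2$area_km2, tolerance = 0.02)
  # centroid of selected cells shifts by (500, -250)
  cc <- function(ct) {
    idx <- which(ct$cells, arr.ind = TRUE)
    c(mean(ct$x[idx[, 1]]), mean(ct$y[idx[, 2]]))
  }
  expect_equal(cc(c2) - cc(c1), c(500, -250), tolerance = 5)
})

test_that("grid refinement changes isopleth areas by less than 5%", {
  set.seed(13)
  tr <- data.frame(x = cumsum(rnorm(40, 0, 15)), y = cumsum(rnorm(40, 0, 15)),
                   t = (1:40) * 60)
  a5 <- ud_contour(bbkud(tr, 0.8, 7.5, cell_size_m = 5), 0.95)$area_km2
  a25 <- ud_contour(bbkud(tr, 0.8, 7.5, cell_size_m = 2.5), 0.95)$area_km2
  expect_lt(abs(a5 - a25) / a25, 0.05)
})

test_that("overlap area: identity, disjointness, and a Monte-Carlo oracle", {
  sq <- function(x0, y0, s) cbind(x = c(x0, x0 + s, x0 + s, x0),
                                  y = c(y0, y0, y0 + s, y0 + s))
  a <- sq(0, 0, 100)
  expect_equal(overlap_area(a, a)$percent_of_b, 100)
  b <- sq(500, 500, 50)
  expect_equal(overlap_area(a, b)$area_km2, 0)
  expect_equal(overlap_area(a, b)$percent_of_b, 0)

  set.seed(14)
  for (i in 1:3) {
    pa <- make_convex_poly(runif(1, -20, 20), runif(1, -20, 20), runif(1, 60, 120))
    pb <- make_convex_poly(runif(1, -20, 20), runif(1, -20, 20), runif(1, 60, 120))
    got <- overlap_area(pa, pb)$area_km2 * 1e6
    bbox <- c(min(pa[, 1], pb[, 1]), max(pa[, 1], pb[, 1]),
              min(pa[, 2], pb[, 2]), max(pa[, 2], pb[, 2]))
    mc <- oracle_mc_overlap(function(x, y) pip(x, y, pa),
                            function(x, y) pip(x, y, pb), bbox)
    expect_lt(abs(got - mc), 0.01 * max(mc, got) + 1e-9)
  }
})

test_that("night activity space exceeds day activity space on generated cohorts", {
  set.seed(15)
  rows <- list()
  for (i in 1:6) {
    cfg <- sim_config(seed = 600 + i)
    sim <- simulate_night_track(cfg)
    tr <- track_xy(filter_detections(sim$track), origin = cfg$site_origin)
    nw <- sim$truth$night_windows[1, ]
    nt <- tr[tr$timestamp >= nw$sunset & tr$timestamp < nw$sunrise, ]
    dt_ <- tr[tr$timestamp < nw$sunset, ]
    an <- activity_space(nt, isopleths = 0.95, thin_s = 120, cell_size_m = 10)
    ad <- activity_space(dt_, isopleths = 0.95, thin_s = 120, cell_size_m = 10)
    rows[[i]] <- data.frame(id = i, night = an$areas_km2[[1]],
                            day = ad$areas_km2[[1]])
  }
  d <- do.call(rbind, rows)
  expect_true(all(d$night > d$day))
})
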