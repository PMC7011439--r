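make_stream <- function(ax, ay, az) data.frame(ax_g = ax, ay_g = ay, az_g = az)

test_that("box-smoother separation: constants, full-cycle sinusoids, oracle, reconstruction", {
  n <- 25 * 20
  const <- make_stream(rep(0.1, n), rep(-0.2, n), rep(1, n))
  sep <- separate_acceleration(const)
  expect_lt(max(abs(as.matrix(sep$dynamic))), 1e-12)

  # the 49-sample window spans exactly two cycles of a 0.98 s sinusoid,
  # so the fitted static component vanishes
  t <- (0:(n - 1)) / 25
  A <- 0.7
  sine <- make_stream(rep(0, n), A * sin(2 * pi * t / 0.98), rep(1, n))
  sep2 <- separate_acceleration(sine)
  core <- 30:(n - 30)
  expect_lt(max(abs(sep2$static$ay_g[core])), 0.01 * A)

  # random stream equals a naive moving-average oracle, and static + dynamic
  # reconstructs the input exactly
  set.seed(30)
  x <- rnorm(400)
  st <- separate_acceleration(make_stream(x, x, x))$static$ax_g
  naive <- vapply(seq_along(x), function(i) {
    h <- min(24, i - 1, length(x) - i)
    mean(x[(i - h):(i + h)])
  }, 0)
  expect_equal(st, naive, tolerance = 1e-12)
  sep3 <- separate_acceleration(make_stream(x, x, x))
  expect_equal(sep3$static$ax_g + sep3$dynamic$ax_g, x, tolerance = 1e-12)

  expect_error(separate_acceleration(make_stream(1:10 / 10, 1:10 / 10, 1:10 / 10)),
               "shorter")
})

test_that("ODBA: zero input, the 2A/pi sinusoid mean, symmetry and scale equivariance", {
  n <- 25 * 60
  z <- make_stream(rep(0, n), rep(0, n), rep(0, n))
  expect_equal(odba(z)$per_sample, rep(0, n))

  t <- (0:(n - 1)) / 25
  A <- 1.3
  for (f in c(0.7, 1.5)) {
    dyn <- make_stream(rep(0, n), A * sin(2 * pi * f * t), rep(0, n))
    m <- mean(odba(dyn)$per_second$odba_g)
    expect_lt(abs(m - 2 * A / pi) / (2 * A / pi), 0.02)
  }

  set.seed(31)
  dyn2 <- make_stream(rnorm(n), rnorm(n), rnorm(n))
  perm <- dyn2[, c(3, 1, 2)]
  names(perm) <- names(dyn2)
  expect_equal(odba(perm)$per_sample, odba(dyn2)$per_sample)
  sc <- dyn2 * -2.5
  expect_equal(odba(sc)$per_sample, 2.5 * odba(dyn2)$per_sample)
})

test_that("wavelet spectrum: tones, silence, two-tone, band validation", {
  n <- 25 * 60
  t <- (0:(n - 1)) / 25
  ws1 <- wavelet_spectrum(sin(2 * pi * t))
  expect_lt(abs(median(ws1$dominant_period) - 1.0), diff(ws1$periods[8:9]))
  expect_gt(median(ws1$peak_amp), 0.9)
  expect_lt(median(ws1$peak_amp), 1.1)

  ws0 <- wavelet_spectrum(rep(0.42, n))
  expect_lt(max(ws0$amp), 0.01)

  x2 <- sin(2 * pi * t / 0.6) + sin(2 * pi * t / 1.6)
  ws2 <- wavelet_spectrum(x2)
  prof <- colMeans(ws2$amp)
  loc <- which(diff(sign(diff(prof))) == -2) + 1
  expect_equal(length(loc), 2)
  expect_lt(abs(ws2$periods[loc[1]] - 0.6), 0.1)
  expect_lt(abs(ws2$periods[loc[2]] - 1.6), 0.2)

  expect_error(wavelet_spectrum(rnorm(100), band = c(0.01, 2)), "band")
})

test_that("dominant tailbeat periods are recovered within one bin at SNR 10", {
  set.seed(32)
  n <- 25 * 120
  t <- (0:(n - 1)) / 25
  for (p in c(0.55, 0.8, 1.2, 1.9)) {
    x <- sin(2 * pi * t / p) + rnorm(n, 0, sqrt(0.5 / 10))
    ws <- wavelet_spectrum(x)
    dom <- median(ws$dominant_period)
    bin <- which.min(abs(ws$periods - p))
    expect_lte(abs(log(dom) - log(ws$periods[bin])),
               diff(log(ws$periods[1:2])) + 1e-9)
  }
})

test_that("ethogram clustering separates two states and is deterministic", {
  set.seed(33)
  fs <- 25; bout <- 300; nb <- 8; nsec <- bout * nb
  truth <- rep(rep(c("rest", "swim"), nb / 2), each = bout)
  A <- ifelse(truth == "rest", 0.02, 0.5)
  t <- (0:(nsec * fs - 1)) / fs
  sway <- rep(A, each = fs) * sin(2 * pi * t) + rnorm(nsec * fs, 0, 0.01)
  ws <- wavelet_spectrum(sway)
  cl <- cluster_ethogram(ws, k = 10, seed = 7)
  act <- classify_activity(cl)
  expect_gte(mean(act$state[truth == "rest"] == "resting"), 0.99)
  expect_gte(mean(act$state[truth == "swim"] == "active"), 0.95)

  cl2 <- cluster_ethogram(ws, k = 10, seed = 7)
  expect_identical(cl$labels, cl2$labels)

  same <- matrix(0.05, nrow = 50, ncol = 16)
  expect_error(cluster_ethogram(same, k = 10), "distinct")
})

test_that("binary classification edge cases", {
  cl <- structure(list(centers = matrix(0, 2, 4), labels = c(1L, 1L, 2L, 2L),
                       resting_ids = c(1L, 2L), k = 2, time = 1:4),
                  class = "ethogram_clusters")
  expect_true(all(classify_activity(cl)$state == "resting"))
  cl$resting_ids <- integer(0)
  expect_true(all(classify_activity(cl)$state == "active"))
})

test_that("hourly resting percentages aggregate correctly", {
  t0 <- as.POSIXct("2017-08-09 00:00:00", tz = "UTC")
  mk <- function(id, sex, resting) {
    data.frame(id = id, sex = sex, time = t0 + 0:(48 * 3600 - 1),
               resting = resting)
  }
  # all resting: 100% every hour, group SE 0 (single individual)
  a <- mk("a", "F", TRUE)
  hr <- hourly_resting(a)
  expect_true(all(hr$individual$pct_resting == 100))
  expect_true(all(hr$group$se_pct_resting == 0))

  # alternating 30 min rest / 30 min active: 50% every hour
  res <- rep(rep(c(TRUE, FALSE), each = 1800), 48)
  b <- mk("b", "M", res)
  hrb <- hourly_resting(b)
  expect_true(all(abs(hrb$individual$pct_resting - 50) < 1e-9))

  # two-individual group mean equals the hand-computed average
  c1 <- mk("c1", "F", TRUE)
  c2 <- mk("c2", "F", rep(rep(c(TRUE, FALSE), each = 1800), 48))
  hrc <- hourly_resting(rbind(c1, c2))
  expect_true(all(abs(hrc$group$mean_pct_resting - 75) < 1e-9))
})
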