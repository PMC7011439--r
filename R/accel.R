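# Acceleration processing: 2 s box-smoother separation of static from
# dynamic acceleration, overall dynamic body acceleration (ODBA), and a
# Morlet continuous-wavelet spectrum of the sway axis summarised per
# second over log-spaced tailbeat-band periods.

# centred moving average with symmetric window shrink at the edges
movmean_shrink <- function(x, half) {
  n <- length(x)
  idx <- seq_len(n)
  hw <- pmin(half, idx - 1, n - idx)
  cs <- c(0, cumsum(x))
  (cs[idx + hw + 1] - cs[idx - hw]) / (2 * hw + 1)
}

#' Separate static from dynamic acceleration
#'
#' Static acceleration per axis is a centred moving average over a 2 s box
#' (an odd number of samples, 49 at 25 Hz; the window shrinks symmetrically
#' at the stream edges), and dynamic acceleration is the raw signal minus
#' the static component, so static + dynamic reconstructs the input
#' exactly.
#'
#' @param stream data.frame with axis columns `ax_g`, `ay_g`, `az_g`.
#' @param window_s smoother window in seconds.
#' @param rate_hz sampling rate.
#' @return list of data.frames `static` and `dynamic` with the same axis
#'   columns.
#' @export
separate_acceleration <- function(stream, window_s = 2, rate_hz = 25) {
  axes <- c("ax_g", "ay_g", "az_g")
  stopifnot(all(axes %in% names(stream)))
  w <- round(window_s * rate_hz)
  if (w %% 2 == 0) w <- w - 1 # odd sample count: 49 at 25 Hz for 2 s
  if (nrow(stream) < w) stop("separate_acceleration: stream shorter than the smoother window")
  half <- (w - 1) / 2
  static <- as.data.frame(lapply(stream[axes], movmean_shrink, half = half))
  dynamic <- as.data.frame(Map(`-`, stream[axes], static))
  list(static = static, dynamic = dynamic)
}

#' Overall dynamic body acceleration
#'
#' Per-sample ODBA is the sum of absolute dynamic accelerations over the
#' three axes; the per-second series is the arithmetic mean of the samples
#' within each clock second.
#'
#' @param dynamic data.frame of dynamic axes (`ax_g`, `ay_g`, `az_g`).
#' @param timestamp optional per-sample times (POSIXct or numeric seconds);
#'   when missing, samples are grouped in blocks of `rate_hz`.
#' @param rate_hz sampling rate, used when `timestamp` is missing.
#' @return list: `per_sample` (numeric vector, g), `per_second`
#'   (data.frame `time`, `odba_g`).
#' @export
odba <- function(dynamic, timestamp = NULL, rate_hz = 25) {
  axes <- intersect(c("ax_g", "ay_g", "az_g"), names(dynamic))
  stopifnot(length(axes) == 3)
  per_sample <- abs(dynamic[[axes[1]]]) + abs(dynamic[[axes[2]]]) +
    abs(dynamic[[axes[3]]])
  sec <- if (is.null(timestamp)) (seq_along(per_sample) - 1) %/% rate_hz else
    floor(as.numeric(timestamp))
  tout <- sort(unique(sec))
  cnt <- as.vector(rowsum(rep(1, length(sec)), sec))
  m <- as.vector(rowsum(per_sample, sec)) / cnt
  per_second <- data.frame(time = tout, odba_g = m)
  if (!is.null(timestamp) && inherits(timestamp, "POSIXct")) {
    per_second$time <- as.POSIXct(per_second$time, origin = "1970-01-01", tz = "UTC")
  }
  list(per_sample = per_sample, per_second = per_second)
}

#' Morlet wavelet spectrum of the sway axis, summarised per second
#'
#' Continuous wavelet transform with the Morlet wavelet (centre frequency
#' parameter 6) at `B` log-spaced Fourier periods within the tailbeat
#' band, computed in the frequency domain. Moduli are normalised so a
#' unit-amplitude sinusoid at an in-band period yields a peak amplitude of
#' 1 g, which makes amplitude thresholds in g meaningful; each second's
#' frame is the time-mean amplitude per period within that second.
#'
#' @param sway sway-axis signal (g) at `rate_hz`; use the dynamic (or raw)
#'   sway — the wavelet band excludes the static component.
#' @param rate_hz sampling rate.
#' @param band period band in seconds (default `c(0.5, 2)`, the range a
#'   full tailbeat takes).
#' @param B number of log-spaced period bins.
#' @param omega0 Morlet centre frequency parameter.
#' @param timestamp optional per-sample times for labelling seconds.
#' @return object of class `spectrum_frames`: `periods` (s), `amp`
#'   (matrix seconds x B, g), `dominant_period`, `peak_amp`, `time`.
#' @export
wavelet_spectrum <- function(sway, rate_hz = 25, band = c(0.5, 2), B = 16,
                             omega0 = 6, timestamp = NULL) {
  n <- length(sway)
  dt <- 1 / rate_hz
  if (band[1] <= 2 * dt || band[2] >= n * dt / 4) {
    stop("wavelet_spectrum: period band outside (2/rate, stream length/4)")
  }
  periods <- exp(seq(log(band[1]), log(band[2]), length.out = B))
  fourier_factor <- 4 * pi / (omega0 + sqrt(2 + omega0^2))
  scales <- periods / fourier_factor
  N <- 2^ceiling(log2(n))
  xpad <- c(sway - mean(sway), rep(0, N - n))
  X <- fft(xpad)
  k <- 0:(N - 1)
  omega <- 2 * pi * ifelse(k <= N / 2, k, k - N) / (N * dt)
  pos <- omega > 0
  sec <- if (is.null(timestamp)) (seq_len(n) - 1) %/% rate_hz else
    floor(as.numeric(timestamp))
  usec <- sort(unique(sec))
  cnt <- as.vector(rowsum(rep(1, n), sec))
  fr <- matrix(0, length(usec), B)
  for (b in seq_len(B)) {
    s <- scales[b]
    psi <- numeric(N)
    psi[pos] <- pi^(-1 / 4) * sqrt(2 * pi * s / dt) *
      exp(-(s * omega[pos] - omega0)^2 / 2)
    W <- fft(X * psi, inverse = TRUE) / N
    # |W| for a unit sinusoid at the matching period is
    # pi^(-1/4) * sqrt(2 pi s / dt) / 2; invert that to report g
    cal <- 2 * pi^(1 / 4) / sqrt(2 * pi * s / dt)
    fr[, b] <- as.vector(rowsum(Mod(W[seq_len(n)]) * cal, sec)) / cnt
  }
  dom <- periods[max.col(fr, ties.method = "first")]
  tout <- usec
  if (!is.null(timestamp) && inherits(timestamp, "POSIXct")) {
    tout <- as.POSIXct(usec, origin = "1970-01-01", tz = "UTC")
  }
  structure(
    list(periods = periods, amp = fr, dominant_period = dom,
         peak_amp = apply(fr, 1, max), time = tout),
    class = "spectrum_frames"
  )
}
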