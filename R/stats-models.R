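# Statistics layer: random-intercept linear mixed models fitted by REML
# for estimates and refitted by ML for AIC/deviance (with Type II Wald
# chi-squared tests per fixed term), the deviance-explained formula, lag-1
# autocorrelation, and penalized-spline smooths with a per-individual
# random intercept and an AR1 error structure for 5-min-mean activity
# series.

#' Random-intercept linear mixed model with deviance explained
#'
#' Fits `response ~ fixed... + (1 | group)` by REML (reported estimates)
#' and by ML (AIC, deviance = -2 maximised log-likelihood), computes Type
#' II Wald chi-squared tests per fixed term, and the percent deviance
#' explained against the intercept-only null model
#' `response ~ 1 + (1 | group)` fitted by ML.
#'
#' @param data model table.
#' @param response response column name.
#' @param fixed character vector of fixed-predictor column names.
#' @param group grouping column name for the random intercept.
#' @return object of class `lme_result`: `estimates`, `wald`
#'   (chi-squared, df, p per term), `AIC`, `deviance`, `null_deviance`,
#'   `deviance_explained`, `singular`, and the fitted `model_ml`,
#'   `model_reml`.
#' @export
fit_lme <- function(data, response, fixed, group) {
  stopifnot(length(unique(data[[group]])) >= 2, is.numeric(data[[response]]))
  fml <- stats::as.formula(paste(
    response, "~", paste(fixed, collapse = " + "), "+ (1 |", group, ")"
  ))
  ml <- lme4::lmer(fml, data = data, REML = FALSE)
  reml <- lme4::lmer(fml, data = data, REML = TRUE)
  has_fixed <- length(setdiff(fixed, "1")) > 0
  wald <- if (has_fixed) as.data.frame(car::Anova(ml, type = 2)) else
    data.frame(Chisq = numeric(), Df = numeric(), `Pr(>Chisq)` = numeric(),
               check.names = FALSE)
  null_f <- stats::as.formula(paste(response, "~ 1 + (1 |", group, ")"))
  null_ml <- lme4::lmer(null_f, data = data, REML = FALSE)
  dev_m <- as.numeric(-2 * logLik(ml))
  dev_0 <- as.numeric(-2 * logLik(null_ml))
  # -2 logLik is negative when residual SDs are < ~0.4 (e.g. responses in
  # km^2); the percent-of-null-deviance summary is then meaningless
  de <- if (dev_0 > 0) deviance_explained(dev_0, dev_m) else NA_real_
  structure(
    list(
      estimates = lme4::fixef(reml),
      wald = wald,
      AIC = AIC(ml),
      deviance = dev_m,
      null_deviance = dev_0,
      deviance_explained = de,
      singular = lme4::isSingular(ml),
      model_ml = ml, model_reml = reml
    ),
    class = "lme_result"
  )
}

#' Percent deviance explained
#'
#' `100 * (null - model) / null`, reported to 2 decimals. A model deviance
#' above the null gives a negative value with a warning.
#'
#' @param null_dev total deviance of the null model (> 0).
#' @param model_dev total deviance of the model.
#' @return percent, rounded to 2 decimals.
#' @export
deviance_explained <- function(null_dev, model_dev) {
  stopifnot(null_dev > 0)
  if (model_dev > null_dev) {
    warning("deviance_explained: model deviance exceeds null deviance")
  }
  round(100 * (null_dev - model_dev) / null_dev, 2)
}

#' Lag-1 autocorrelation
#'
#' Sample autocorrelation at lag 1, mean-centred with the biased
#' (denominator n) normalisation.
#'
#' @param series numeric vector, length >= 10.
#' @return correlation coefficient phi.
#' @export
acf_lag1 <- function(series) {
  x <- as.numeric(series)
  if (length(x) < 10) stop("acf_lag1: need at least 10 points")
  m <- mean(x)
  n <- length(x)
  sum((x[-1] - m) * (x[-n] - m)) / sum((x - m)^2)
}

# pooled within-block lag-1 autocorrelation of a residual vector
blocked_acf_lag1 <- function(res, block) {
  m <- mean(res)
  num <- 0; den <- sum((res - m)^2)
  for (b in unique(block)) {
    r <- res[block == b]
    if (length(r) > 1) num <- num + sum((r[-1] - m) * (r[-length(r)] - m))
  }
  num / den
}

#' Smooth activity model with random intercept and AR1 errors
#'
#' Penalized regression-spline fit of a 5-min-mean activity series on one
#' predictor (cyclic cubic basis for time of day, cubic otherwise, default
#' 8 basis functions) with a per-individual random intercept. Residual
#' temporal autocorrelation is handled by an AR1 working correlation whose
#' coefficient is the pooled within-series lag-1 autocorrelation of the
#' residuals of a first-pass fit; smoothing is chosen by GCV.
#'
#' @param data table of 5-min means with columns `id`, the predictor, and
#'   the response; rows ordered in time within each AR block.
#' @param predictor one of `"time_of_day"` (hours, cyclic over 24; for
#'   full-diel series), `"hours_after_sunset"` (the natural time axis for
#'   nighttime-only series: continuous through midnight, cubic basis),
#'   `"temperature"`, `"depth"`, or any numeric column name (non-cyclic).
#' @param response response column (default `"odba_g"`).
#' @param block optional column naming contiguous AR1 blocks (default:
#'   `id`); elapsed time is assumed ordered within blocks.
#' @param k spline basis dimension. The default resolves features wider
#'   than about 1/(k-2) of the predictor range; raise it for narrow
#'   features such as brief transit bouts.
#' @param phi optional fixed AR1 coefficient; when `NULL` it is estimated
#'   as the pooled within-block lag-1 autocorrelation of first-pass
#'   residuals. `phi = 0` reduces to the ordinary (no-AR1) fit.
#' @return object of class `smooth_fit`: `grid` (predictor, fit, se, lo,
#'   hi), `phi`, `F`, `p_value`, `edf`, `model`.
#' @export
fit_activity_smooth <- function(data, predictor, response = "odba_g",
                                block = NULL, k = 8, phi = NULL) {
  stopifnot(predictor %in% names(data), response %in% names(data))
  if (length(unique(data[[predictor]])) < 3) {
    stop("fit_activity_smooth: predictor is (nearly) constant")
  }
  d <- data
  d$id <- factor(d$id)
  d$.y <- d[[response]]
  d$.x <- d[[predictor]]
  blk <- if (is.null(block)) as.character(d$id) else as.character(d[[block]])
  cyclic <- identical(predictor, "time_of_day")
  bs <- if (cyclic) "cc" else "cr"
  knots <- if (cyclic) list(.x = c(0, 24)) else NULL
  fml <- if (nlevels(d$id) > 1) {
    .y ~ s(.x, bs = bs, k = k) + s(id, bs = "re")
  } else {
    .y ~ s(.x, bs = bs, k = k)
  }
  m0 <- mgcv::bam(fml, data = d, method = "GCV.Cp", knots = knots)
  if (is.null(phi)) phi <- blocked_acf_lag1(resid(m0), blk)
  ar_start <- !duplicated(blk)
  m1 <- mgcv::bam(fml, data = d, method = "GCV.Cp", knots = knots,
                  rho = phi, AR.start = ar_start)
  xg <- if (cyclic) seq(0, 24, by = 0.05) else
    seq(min(d$.x), max(d$.x), length.out = 400)
  nd <- data.frame(.x = xg, id = d$id[1])
  pr <- predict(m1, newdata = nd, se.fit = TRUE,
                exclude = if (nlevels(d$id) > 1) "s(id)" else NULL,
                newdata.guaranteed = TRUE)
  st <- summary(m1)$s.table
  grid <- data.frame(
    predictor = xg, fit = as.numeric(pr$fit), se = as.numeric(pr$se.fit)
  )
  grid$lo <- grid$fit - 1.96 * grid$se
  grid$hi <- grid$fit + 1.96 * grid$se
  structure(
    list(grid = grid, phi = phi,
         F = st[1, "F"], p_value = st[1, "p-value"], edf = st[1, "edf"],
         cyclic = cyclic, model = m1),
    class = "smooth_fit"
  )
}

#' Local maxima of a fitted smooth
#'
#' Finds local maxima of the fitted curve and filters them by topographic
#' prominence (the drop to the higher of the two flanking valleys, walking
#' outwards until terrain higher than the peak is met), so numerical
#' micro-wiggle on flat stretches does not register. Peaks are returned
#' ordered by fitted value, highest first.
#'
#' @param sf a [fit_activity_smooth()] result.
#' @param min_prominence minimum prominence as a fraction of the fitted
#'   range.
#' @return data.frame `predictor`, `fit`, `prominence`.
#' @export
smooth_peaks <- function(sf, min_prominence = 0.1) {
  g <- sf$grid
  y <- g$fit
  n <- length(y)
  idx <- which(y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] >= y[3:n]) + 1
  rng <- diff(range(y))
  if (!length(idx) || rng <= 0) {
    return(data.frame(predictor = numeric(), fit = numeric(),
                      prominence = numeric()))
  }
  prom <- vapply(idx, function(i) {
    lm_ <- y[i]; j <- i
    while (j > 1 && y[j] <= y[i]) { j <- j - 1; lm_ <- min(lm_, y[j]) }
    rm_ <- y[i]; j <- i
    while (j < n && y[j] <= y[i]) { j <- j + 1; rm_ <- min(rm_, y[j]) }
    y[i] - max(lm_, rm_)
  }, 0)
  keep <- prom / rng >= min_prominence
  out <- data.frame(predictor = g$predictor[idx[keep]], fit = y[idx[keep]],
                    prominence = prom[keep])
  out[order(-out$fit), , drop = FALSE]
}

#' Window means of a per-second series
#'
#' Aggregates a per-second table into fixed windows (5 min by default) per
#' id; on complete windows the mean of the aggregated series equals the
#' mean of the raw series.
#'
#' @param df data.frame with `id`, `time` (POSIXct or numeric seconds) and
#'   value columns.
#' @param cols columns to average.
#' @param window_s window length in seconds.
#' @return data.frame `id`, `time` (window start), and window means.
#' @export
aggregate_window <- function(df, cols, window_s = 300) {
  w <- floor(as.numeric(df$time) / window_s) * window_s
  out <- aggregate(df[cols], by = list(id = df$id, time = w), FUN = mean)
  out <- out[order(out$id, out$time), , drop = FALSE]
  rownames(out) <- NULL
  out
}
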