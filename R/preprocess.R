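#' Preprocessing filter configuration
#'
#' Settings for the three-stage cleaning chain applied to every channel:
#' artifact flagging with median interpolation, non-overlapping
#' moving-average downsampling to 2 Hz, then a modality-specific smoother
#' (one-Euro for electrodermal activity, exponential decay for skin
#' temperature, cubic smoothing spline for heart rate).
#'
#' @param median_order_eda Median interpolation window for EDA, samples.
#' @param median_order_temp Median interpolation window for temperature,
#'   samples.
#' @param median_order_hr Median interpolation window for heart rate,
#'   samples.
#' @param oneeuro_mincutoff One-Euro minimum cutoff (Hz-like).
#' @param oneeuro_beta One-Euro speed coefficient.
#' @param oneeuro_dcutoff One-Euro derivative low-pass cutoff, Hz.
#' @param expdecay_p Exponential decay smoothing parameter in `[0, 1]`.
#' @param spline_p Smoothing-spline parameter in `[0, 1]` (csaps
#'   convention: `p` multiplies the fidelity term).
#' @param ma_window_s Moving-average window, seconds.
#' @return A `filter_config` list.
#' @export
filter_config <- function(median_order_eda = 75, median_order_temp = 1,
                          median_order_hr = 1,
                          oneeuro_mincutoff = 50, oneeuro_beta = 4,
                          oneeuro_dcutoff = 1,
                          expdecay_p = 0.95, spline_p = 0.001,
                          ma_window_s = 0.5) {
  cfg <- list(median_order_eda = median_order_eda,
              median_order_temp = median_order_temp,
              median_order_hr = median_order_hr,
              oneeuro_mincutoff = oneeuro_mincutoff,
              oneeuro_beta = oneeuro_beta,
              oneeuro_dcutoff = oneeuro_dcutoff,
              expdecay_p = expdecay_p, spline_p = spline_p,
              ma_window_s = ma_window_s)
  if (cfg$median_order_eda < 1 || cfg$median_order_temp < 1 ||
      cfg$median_order_hr < 1) {
    abort("median filter orders must be >= 1",
          class = "physioevents_validation_error")
  }
  if (cfg$expdecay_p < 0 || cfg$expdecay_p > 1 ||
      cfg$spline_p < 0 || cfg$spline_p > 1) {
    abort("smoothing parameters must lie in [0, 1]",
          class = "physioevents_validation_error")
  }
  if (cfg$ma_window_s <= 0) {
    abort("ma_window_s must be positive", class = "physioevents_validation_error")
  }
  structure(cfg, class = "filter_config")
}

#' Flag hardware-error samples
#'
#' Marks samples that are exact zeros (sensor dropout) or that deviate by
#' more than three standard deviations from the mean of the preceding one
#' second of data. The two rules are combined by OR. Samples with fewer
#' than two preceding samples are never flagged by the deviation rule, and
#' the rule is skipped when the preceding window has zero variance (a
#' clean constant signal must not flag itself).
#'
#' @param x Numeric channel series.
#' @param t Time axis in seconds, same length as `x`.
#' @param sd_mult Deviation multiple (default 3).
#' @param lookback_s Length of the preceding window, seconds (default 1).
#' @return Logical mask, `TRUE` where a sample is artifactual.
#' @export
flag_artifacts <- function(x, t, sd_mult = 3, lookback_s = 1) {
  n <- length(x)
  if (n == 0) abort("empty input", class = "physioevents_domain_error")
  stopifnot(length(t) == n)
  mask <- x == 0
  if (n < 3) return(mask)
  fs <- 1 / median(diff(t))
  w <- max(2L, as.integer(round(fs * lookback_s)))
  ## preceding-window mean/sd via cumulative sums (window excludes current)
  cs <- c(0, cumsum(x))       # cs[i + 1] = sum of x[1..i]
  cs2 <- c(0, cumsum(x^2))
  i <- seq_len(n)
  lo <- pmax(i - w, 1L)       # first index of the preceding window
  k <- i - lo                 # number of preceding samples available
  sum_w <- cs[i] - cs[lo]
  sum2_w <- cs2[i] - cs2[lo]
  mu <- sum_w / k
  varw <- pmax(sum2_w / k - mu^2, 0)
  sdw <- sqrt(varw * k / pmax(k - 1, 1))   # sample SD of preceding window
  dev_rule <- k >= 2 & sdw > 0 & abs(x - mu) > sd_mult * sdw
  dev_rule[is.na(dev_rule)] <- FALSE
  mask | dev_rule
}

#' Replace flagged samples by a windowed median of clean neighbours
#'
#' Each flagged sample becomes the median of the unflagged samples inside
#' a centred window of `order` samples (even orders are rounded up to the
#' next odd number). If a run of flagged samples exhausts the window, the
#' nearest unflagged sample's value is used as a fallback. Unflagged
#' samples pass through unchanged.
#'
#' @param x Numeric series.
#' @param mask Logical mask from [flag_artifacts()].
#' @param order Window length in samples.
#' @return Numeric series with flagged samples repaired.
#' @export
interpolate_median <- function(x, mask, order = 75) {
  n <- length(x)
  stopifnot(length(mask) == n, order >= 1)
  if (all(mask)) {
    abort("all samples flagged; nothing to interpolate from",
          class = "physioevents_domain_error")
  }
  if (!any(mask)) return(x)
  order <- as.integer(order)
  if (order %% 2L == 0L) order <- order + 1L
  half <- order %/% 2L
  good_idx <- which(!mask)
  y <- x
  for (i in which(mask)) {
    lo <- max(1L, i - half); hi <- min(n, i + half)
    nb <- good_idx[good_idx >= lo & good_idx <= hi]
    if (length(nb) > 0) {
      y[i] <- median(x[nb])
    } else {
      nearest <- good_idx[which.min(abs(good_idx - i))]
      y[i] <- x[nearest]
    }
  }
  y
}

#' Downsample by a non-overlapping moving average
#'
#' Averages consecutive, non-overlapping windows of `window_s` seconds
#' aligned to the first sample; a trailing partial window is discarded.
#' Windows are delimited in time, so a non-integer `fs * window_s` (e.g.
#' 7.5 samples at 15 Hz with the default 0.5-second window) alternates
#' window sizes and the output rate is exactly `1 / window_s` (2 Hz by
#' default).
#'
#' @param x Numeric series.
#' @param fs Input sampling rate, Hz.
#' @param window_s Window length, seconds.
#' @return Numeric series of length `floor(length(x) / (fs * window_s))`.
#' @export
downsample_movavg <- function(x, fs, window_s = 0.5) {
  spw <- fs * window_s
  if (spw < 1) abort("fs * window_s must be >= 1", class = "physioevents_domain_error")
  n <- length(x)
  n_out <- floor(n / spw + .thr_eps)
  if (n_out == 0) {
    warn("input shorter than one window; empty output")
    return(numeric(0))
  }
  ## sample i (0-based) belongs to the window containing time i/fs
  bin <- floor((seq_len(n) - 1) / spw + .thr_eps)
  keep <- bin < n_out
  as.numeric(tapply(x[keep], bin[keep], mean))
}

#' One-Euro adaptive low-pass filter
#'
#' Speed-adaptive exponential smoothing: the cutoff of a first-order
#' low-pass is raised in proportion to the (low-passed) signal speed,
#' `cutoff = mincutoff + beta * |dx|`, trading lag for jitter. Applied to
#' the 2 Hz electrodermal channel.
#'
#' @param x Numeric series.
#' @param rate Sampling rate of `x`, Hz.
#' @param mincutoff Minimum cutoff (Hz-like tuning parameter).
#' @param beta Speed coefficient.
#' @param dcutoff Cutoff of the derivative low-pass, Hz.
#' @return Filtered series, same length.
#' @export
one_euro <- function(x, rate = 2, mincutoff = 50, beta = 4, dcutoff = 1) {
  n <- length(x)
  if (n == 0) abort("empty input", class = "physioevents_domain_error")
  alpha <- function(cutoff) {
    tau <- 1 / (2 * pi * cutoff)
    1 / (1 + tau * rate)
  }
  y <- numeric(n)
  y[1] <- x[1]
  dx_hat <- 0
  a_d <- alpha(dcutoff)
  for (k in seq_len(n)[-1]) {
    dx <- (x[k] - y[k - 1]) * rate
    dx_hat <- a_d * dx + (1 - a_d) * dx_hat
    a <- alpha(mincutoff + beta * abs(dx_hat))
    y[k] <- a * x[k] + (1 - a) * y[k - 1]
  }
  y
}

#' Exponential decay smoother
#'
#' First-order recursive smoothing `y[k] = p * y[k-1] + (1 - p) * x[k]`
#' with `y[1] = x[1]`; applied to the 2 Hz skin-temperature channel to
#' remove high-frequency noise.
#'
#' @param x Numeric series.
#' @param p Smoothing parameter in `[0, 1]` (0 = no smoothing, 1 = freeze
#'   at the first sample).
#' @return Filtered series, same length.
#' @export
exp_decay <- function(x, p = 0.95) {
  stopifnot(p >= 0, p <= 1)
  n <- length(x)
  if (n == 0) return(x)
  if (p == 1) return(rep(x[1], n))
  ## y = (1-p) * filter(x, p, recursive) with y[1] forced to x[1]:
  ## implement directly via stats::filter for speed
  y <- stats::filter(c(x[1] / (1 - p), x[-1]), p, method = "recursive",
                     init = 0)
  y <- as.numeric(y) * (1 - p)
  y[1] <- x[1]
  y
}

#' Cubic smoothing spline (csaps convention)
#'
#' Fits the natural cubic smoothing spline minimizing
#' `p * sum((y - x)^2) + (1 - p) * integral(y'')^2` over the original time
#' axis and evaluates it at the input times. `p = 1` interpolates, `p = 0`
#' gives the least-squares straight line. Applied to the 2 Hz heart-rate
#' channel.
#'
#' @param x Numeric series (ordinates).
#' @param t2 Time axis, seconds, strictly increasing, same length.
#' @param p Smoothing parameter in `[0, 1]`.
#' @return Smoothed series, same length.
#' @export
smooth_spline_csaps <- function(x, t2, p = 0.001) {
  n <- length(x)
  stopifnot(length(t2) == n, p >= 0, p <= 1)
  if (n < 4) abort("smoothing spline needs >= 4 points",
                   class = "physioevents_domain_error")
  if (p == 1) return(x)
  if (p == 0) {
    fit <- lm(x ~ t2)
    return(as.numeric(fit$fitted.values))
  }
  ## smooth.spline rescales t to [0,1]; the curvature integral picks up a
  ## factor range^-3, hence lambda below realizes the csaps criterion
  r <- diff(range(t2))
  lambda <- (1 - p) / (p * r^3)
  fit <- smooth.spline(t2, x, lambda = lambda, all.knots = TRUE,
                       keep.data = FALSE)
  predict(fit, t2)$y
}

#' Clean and downsample a recording
#'
#' Runs each channel through artifact flagging, median interpolation
#' (order 75 for electrodermal activity, 1 for temperature and heart
#' rate), non-overlapping moving-average downsampling, then the
#' modality-specific smoother. The result is the 2 Hz `clean_signals`
#' tibble consumed by the quality and detection stages.
#'
#' @param rec A [physio_recording()].
#' @param cfg A [filter_config()].
#' @return A `clean_signals` tibble with columns `time_s`, `eda_us`,
#'   `temp_c`, `hr_bpm` at `1 / ma_window_s` Hz (window-start times).
#' @export
preprocess <- function(rec, cfg = filter_config()) {
  stopifnot(inherits(rec, "physio_recording"))
  fs <- recording_fs(rec)
  t <- rec$time_s
  clean_channel <- function(x, order) {
    mask <- flag_artifacts(x, t)
    x2 <- interpolate_median(x, mask, order = order)
    downsample_movavg(x2, fs, cfg$ma_window_s)
  }
  eda2 <- clean_channel(rec$eda_us, cfg$median_order_eda)
  temp2 <- clean_channel(rec$temp_c, cfg$median_order_temp)
  hr2 <- clean_channel(rec$hr_bpm, cfg$median_order_hr)
  rate <- 1 / cfg$ma_window_s
  t2 <- t[1] + (seq_along(eda2) - 1) * cfg$ma_window_s
  eda_f <- one_euro(eda2, rate = rate, mincutoff = cfg$oneeuro_mincutoff,
                    beta = cfg$oneeuro_beta, dcutoff = cfg$oneeuro_dcutoff)
  temp_f <- exp_decay(temp2, p = cfg$expdecay_p)
  hr_f <- if (length(hr2) >= 4) {
    smooth_spline_csaps(hr2, t2, p = cfg$spline_p)
  } else {
    hr2
  }
  structure(tibble::tibble(time_s = t2, eda_us = eda_f,
                           temp_c = temp_f, hr_bpm = hr_f),
            fs = rate, session_id = attr(rec, "session_id"),
            class = c("clean_signals", class(tibble::tibble())))
}
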