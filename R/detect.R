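## trailing-window running minimum / maximum over w samples (inclusive of
## the current sample), vectorized with a monotone deque
.run_extreme <- function(x, w, which = c("min", "max")) {
  which <- match.arg(which)
  sgn <- if (which == "min") 1 else -1
  z <- sgn * x
  n <- length(z)
  out <- numeric(n)
  dq <- integer(n); hd <- 1L; tl <- 0L
  for (i in seq_len(n)) {
    while (tl >= hd && z[dq[tl]] >= z[i]) tl <- tl - 1L
    tl <- tl + 1L; dq[tl] <- i
    if (dq[hd] <= i - w) hd <- hd + 1L
    out[i] <- z[dq[hd]]
  }
  sgn * out
}

#' Electrodermal-reaction feature series
#'
#' An electrodermal reaction (EDR) is a transient rise in skin
#' conductance; canonically at least 0.05 uS within 10 seconds. At each
#' 0.5-second step the rise is measured as the current value minus the
#' minimum over the trailing `t_edr`-second window; the feature strength
#' is that rise (in microsiemens) when it reaches `a_edr`, and 0
#' otherwise.
#'
#' @param eda 2 Hz cleaned electrodermal series, microsiemens.
#' @param t_edr Search window, seconds (>= 1).
#' @param a_edr Minimum amplitude, microsiemens.
#' @param step_s Sample spacing of `eda`, seconds.
#' @return Non-negative feature series, aligned to the input.
#' @export
detect_edr <- function(eda, t_edr = 10, a_edr = 0.05, step_s = 0.5) {
  stopifnot(t_edr >= 1)
  n <- length(eda)
  if (n == 0) return(numeric(0))
  w <- as.integer(round(t_edr / step_s)) + 1L  # window [t - t_edr, t]
  rise <- eda - .run_extreme(eda, w, "min")
  ifelse(rise >= a_edr - .thr_eps, rise, 0)
}

#' Temperature trend-excursion feature series
#'
#' Fingertip vasoconstriction and vasodilation appear as cooling and
#' warming trends. At each step the range (max minus min, degrees
#' Celsius) of the trailing `t_temp`-second window is computed; the
#' feature strength is that range when it reaches `dt_min`, else 0. In
#' `"reversal"` mode the window must additionally contain a slope sign
#' change (a switch between cooling and warming); the default `"range"`
#' mode fires on the range alone.
#'
#' @param temp 2 Hz cleaned temperature series, degrees Celsius.
#' @param t_temp Trend window, seconds (>= 1).
#' @param dt_min Minimum range, degrees Celsius.
#' @param mode `"range"` or `"reversal"`.
#' @param step_s Sample spacing, seconds.
#' @return Non-negative feature series, aligned to the input.
#' @export
detect_temp_trend <- function(temp, t_temp = 10, dt_min = 0.01,
                              mode = c("range", "reversal"), step_s = 0.5) {
  mode <- match.arg(mode)
  stopifnot(t_temp >= 1)
  n <- length(temp)
  if (n == 0) return(numeric(0))
  w <- as.integer(round(t_temp / step_s)) + 1L
  rng <- .run_extreme(temp, w, "max") - .run_extreme(temp, w, "min")
  fired <- rng >= dt_min - .thr_eps
  if (mode == "reversal" && n >= 3) {
    s <- sign(diff(temp))
    ## nonzero-slope sign change at diff positions j vs previous nonzero
    last_nonzero <- s
    for (j in seq_along(s)[-1]) {
      if (last_nonzero[j] == 0) last_nonzero[j] <- last_nonzero[j - 1]
    }
    flip <- c(FALSE, s[-1] != 0 & last_nonzero[-length(s)] != 0 &
                s[-1] != last_nonzero[-length(s)])
    ## step i fires only if a flip occurred within its trailing window
    cs <- cumsum(flip)
    has_flip <- rep(FALSE, n)
    i <- 2:n
    lo <- pmax(i - w + 1L, 2L)
    has_flip[i] <- (cs[i - 1L] - c(0, cs)[lo - 1L]) > 0
    fired <- fired & has_flip
  }
  ifelse(fired, rng, 0)
}

## topographic prominence of interior local maxima; bases found as the
## lowest point between the peak and the next higher sample on each side
.peak_prominences <- function(x) {
  n <- length(x)
  if (n < 3) return(list(idx = integer(0), prom = numeric(0)))
  idx <- which(diff(sign(diff(x))) < 0) + 1L
  ## plateau peaks: rising then flat then falling; take first plateau sample
  if (length(idx) == 0) {
    d <- diff(x)
    rises <- which(d > 0)
    idx <- integer(0)
    for (i in rises) {
      j <- i + 1L
      while (j < n && x[j + 1L] == x[i + 1L]) j <- j + 1L
      if (j < n && x[j + 1L] < x[i + 1L]) idx <- c(idx, i + 1L)
    }
    idx <- unique(idx)
  }
  prom <- vapply(idx, function(i) {
    pk <- x[i]
    lmin <- pk
    j <- i - 1L
    while (j >= 1L && x[j] <= pk) { lmin <- min(lmin, x[j]); j <- j - 1L }
    rmin <- pk
    j <- i + 1L
    while (j <= n && x[j] <= pk) { rmin <- min(rmin, x[j]); j <- j + 1L }
    pk - max(lmin, rmin)
  }, numeric(1))
  list(idx = idx, prom = prom)
}

#' Heart-rate variation feature series
#'
#' Flags heart-rate accelerations and decelerations that stand out from
#' the baseline pattern: local maxima and minima (minima via peak-finding
#' on the negated series) whose topographic prominence reaches
#' `min_peak_prominence`. The feature strength is the prominence (bpm) at
#' peak locations and 0 elsewhere; end samples are never peaks.
#'
#' @param hr 2 Hz cleaned heart-rate series, bpm.
#' @param min_peak_prominence Prominence threshold, bpm.
#' @return Non-negative feature series, aligned to the input.
#' @export
detect_hr_var <- function(hr, min_peak_prominence = 10) {
  n <- length(hr)
  out <- numeric(n)
  if (n < 3) return(out)
  for (sgn in c(1, -1)) {
    pk <- .peak_prominences(sgn * hr)
    keep <- pk$prom >= min_peak_prominence - .thr_eps
    out[pk$idx[keep]] <- pmax(out[pk$idx[keep]], pk$prom[keep])
  }
  out
}

#' Extract all three feature series from a cleaned session
#'
#' @param clean A `clean_signals` tibble from [preprocess()].
#' @param params A [detector_params()] object.
#' @return A `feature_series` tibble with columns `time_s`, `edr`,
#'   `dtemp`, `hrvar` (all non-negative, zero where the underlying
#'   feature does not cross its threshold).
#' @export
detect_features <- function(clean, params = detector_params()) {
  step_s <- clean$time_s[2] - clean$time_s[1]
  structure(tibble::tibble(
    time_s = clean$time_s,
    edr = detect_edr(clean$eda_us, params$t_edr, params$a_edr, step_s),
    dtemp = detect_temp_trend(clean$temp_c, params$t_temp, params$dt_min,
                              params$temp_mode, step_s),
    hrvar = detect_hr_var(clean$hr_bpm, params$min_peak_prominence)),
    class = c("feature_series", class(tibble::tibble())))
}

#' Weighted salience score
#'
#' Combines the three feature series into the scalar salience score
#' `S(t) = a * EDR(t) + b * dTemp(t) + c * HRvar(t)` with non-negative
#' modality weights, and records the dominant modality (argmax of the
#' weighted terms) at each step.
#'
#' @param features A `feature_series` tibble from [detect_features()].
#' @param weight_eda,weight_temp,weight_hr Non-negative weights.
#' @return A `score_series` tibble with columns `time_s`, `score`,
#'   `dominant_modality`.
#' @export
score_features <- function(features, weight_eda = 1, weight_temp = 1,
                           weight_hr = 1) {
  if (weight_eda < 0 || weight_temp < 0 || weight_hr < 0) {
    abort("weights must be non-negative", class = "physioevents_validation_error")
  }
  terms <- cbind(eda = weight_eda * features$edr,
                 temp = weight_temp * features$dtemp,
                 hr = weight_hr * features$hrvar)
  dom <- colnames(terms)[max.col(terms, ties.method = "first")]
  structure(tibble::tibble(time_s = features$time_s,
                           score = rowSums(terms),
                           dominant_modality = dom),
            class = c("score_series", class(tibble::tibble())))
}

#' Select the top-scoring, quality-valid, well-separated events
#'
#' Greedy selection: repeatedly take the highest-score step with a
#' positive score and a valid quality mask that is not within `min_sep_s`
#' of an already selected event, until `n_max` events are chosen or no
#' candidate remains. Ties are broken toward the earlier time. Each event
#' carries its dominant modality and video-clip window.
#'
#' @param scores A `score_series` tibble from [score_features()].
#' @param sqi_all Binary validity series aligned to `scores` (1 = valid),
#'   or `NULL` to accept every step.
#' @param n_max Maximum number of events.
#' @param min_sep_s Minimum separation between events, seconds.
#' @param clip_halfwidth_s Clip half-width, seconds.
#' @param span Recording span for clip truncation; defaults to the score
#'   series' own time range.
#' @return An [event_table()] sorted by time.
#' @export
select_events <- function(scores, sqi_all = NULL, n_max = 5, min_sep_s = 20,
                          clip_halfwidth_s = 10, span = NULL) {
  if (is.null(span)) span <- range(scores$time_s)
  ok <- scores$score > 0
  if (!is.null(sqi_all)) {
    stopifnot(length(sqi_all) == nrow(scores))
    ok <- ok & sqi_all == 1
  }
  cand <- which(ok)
  chosen <- integer(0)
  if (length(cand) > 0 && n_max > 0) {
    ord <- cand[order(-scores$score[cand], scores$time_s[cand])]
    for (i in ord) {
      if (length(chosen) >= n_max) break
      if (all(abs(scores$time_s[i] - scores$time_s[chosen]) >= min_sep_s)) {
        chosen <- c(chosen, i)
      }
    }
  }
  chosen <- chosen[order(scores$time_s[chosen])]
  if (length(chosen) == 0) return(event_table())
  cw <- clip_window(scores$time_s[chosen], span, clip_halfwidth_s)
  event_table(tibble::tibble(
    time_s = scores$time_s[chosen],
    score = scores$score[chosen],
    dominant_modality = scores$dominant_modality[chosen],
    clip_start_s = cw$clip_start_s, clip_end_s = cw$clip_end_s))
}

#' Run the full event detector on a cleaned, quality-scored session
#'
#' Composes feature extraction, weighted scoring and greedy top-N
#' selection on quality-valid steps.
#'
#' @param clean A `clean_signals` tibble from [preprocess()].
#' @param sqi An `sqi_series` tibble from [compute_sqi()], or `NULL` to
#'   skip quality gating.
#' @param params A [detector_params()] object.
#' @return An [event_table()].
#' @export
run_detector <- function(clean, sqi = NULL, params = detector_params()) {
  feats <- detect_features(clean, params)
  sc <- score_features(feats, params$weight_eda, params$weight_temp,
                       params$weight_hr)
  select_events(sc, sqi_all = if (is.null(sqi)) NULL else sqi$sqi_all,
                n_max = params$max_events, min_sep_s = params$min_sep_s,
                clip_halfwidth_s = params$clip_halfwidth_s,
                span = range(clean$time_s))
}

#' End-to-end detection from a raw recording
#'
#' Convenience wrapper: [preprocess()] then [compute_sqi()] then
#' [run_detector()].
#'
#' @param rec A [physio_recording()].
#' @param params A [detector_params()] object.
#' @param cfg A [filter_config()].
#' @param rules An [sqi_rules()] object.
#' @return An [event_table()].
#' @export
detect_events <- function(rec, params = detector_params(),
                          cfg = filter_config(), rules = sqi_rules()) {
  clean <- preprocess(rec, cfg)
  sqi <- compute_sqi(clean, rules)
  run_detector(clean, sqi, params)
}
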