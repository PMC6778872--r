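#' Signal-quality rule set
#'
#' Thresholds and scores of the rule-based signal-quality index. Each rule
#' that fires at a 0.5-second step proposes a score; the step's SQI is the
#' minimum over fired rules (worst evidence dominates), or 1 when none
#' fire. Electrodermal rules: a consecutive-sample change larger than 3 uS
#' anywhere in the trailing 15 s window scores 0.4; a flat trailing 25 s
#' window (all consecutive differences at most 0.001 uS) scores 0.1;
#' values at or below 0.02 uS score 0, above 20 uS score 0.65, above
#' 30 uS score 0. Temperature rules: a flat trailing 25 s window
#' (differences at most 0.0001 degC) scores 0.5; values below 15 degC
#' score 0.5. During warm-up (before a rule's window has fully elapsed)
#' only the instantaneous range rules are evaluated.
#'
#' @param eda_deriv_window_s,eda_deriv_thresh,eda_deriv_score
#'   Electrodermal rate-of-change rule.
#' @param eda_flat_window_s,eda_flat_eps,eda_flat_score
#'   Electrodermal flatness rule.
#' @param eda_low,eda_low_score Low physiological bound for EDA.
#' @param eda_high1,eda_high1_score,eda_high2,eda_high2_score
#'   Tiered high bounds for EDA (the more extreme tier wins via min).
#' @param temp_flat_window_s,temp_flat_eps,temp_flat_score
#'   Temperature flatness rule.
#' @param temp_low,temp_low_score Low physiological bound for temperature.
#' @param step_s Evaluation step, seconds.
#' @return An `sqi_rules` list.
#' @export
sqi_rules <- function(eda_deriv_window_s = 15, eda_deriv_thresh = 3,
                      eda_deriv_score = 0.4,
                      eda_flat_window_s = 25, eda_flat_eps = 0.001,
                      eda_flat_score = 0.1,
                      eda_low = 0.02, eda_low_score = 0,
                      eda_high1 = 20, eda_high1_score = 0.65,
                      eda_high2 = 30, eda_high2_score = 0,
                      temp_flat_window_s = 25, temp_flat_eps = 0.0001,
                      temp_flat_score = 0.5,
                      temp_low = 15, temp_low_score = 0.5,
                      step_s = 0.5) {
  r <- as.list(environment())
  if (r$eda_deriv_window_s <= 0 || r$eda_flat_window_s <= 0 ||
      r$temp_flat_window_s <= 0 || r$step_s <= 0) {
    abort("rule windows must be positive", class = "physioevents_validation_error")
  }
  if (r$eda_high1 >= r$eda_high2) {
    abort("eda_high1 must be below eda_high2",
          class = "physioevents_validation_error")
  }
  structure(r, class = "sqi_rules")
}

## TRUE at step i when every consecutive difference within the trailing
## window of `w` samples is <= eps; NA during warm-up
.trailing_flat <- function(x, w, eps) {
  n <- length(x)
  small <- abs(diff(x)) <= eps + .thr_eps        # length n - 1
  out <- rep(NA, n)
  if (n <= w) return(out)
  ## step i looks at diffs (i-w) .. (i-1)
  cs <- cumsum(small)
  i <- (w + 1L):n
  cnt <- cs[i - 1L] - c(0, cs)[i - w]
  out[i] <- cnt == w
  out
}

#' Electrodermal signal-quality series
#'
#' @param eda 2 Hz electrodermal series, microsiemens.
#' @param rules An [sqi_rules()] object.
#' @return Numeric SQI series in `[0, 1]`, aligned to the input.
#' @export
sqi_eda <- function(eda, rules = sqi_rules()) {
  n <- length(eda)
  if (n == 0) return(numeric(0))
  per_step <- 1 / rules$step_s
  score <- matrix(1, nrow = n, ncol = 5)
  ## range rules (instantaneous; no warm-up)
  score[eda <= rules$eda_low + .thr_eps, 1] <- rules$eda_low_score
  score[eda > rules$eda_high1, 2] <- rules$eda_high1_score
  score[eda > rules$eda_high2, 3] <- rules$eda_high2_score
  ## derivative rule: any consecutive jump > thresh inside trailing window
  wd <- as.integer(round(rules$eda_deriv_window_s * per_step))
  if (n > wd) {
    big <- abs(diff(eda)) > rules$eda_deriv_thresh
    cs <- cumsum(big)
    i <- (wd + 1L):n
    fired <- (cs[i - 1L] - c(0, cs)[i - wd]) > 0
    score[i, 4][fired] <- rules$eda_deriv_score
  }
  ## flatness rule over trailing window
  wf <- as.integer(round(rules$eda_flat_window_s * per_step))
  flat <- .trailing_flat(eda, wf, rules$eda_flat_eps)
  score[which(flat %in% TRUE), 5] <- rules$eda_flat_score
  apply(score, 1, min)
}

#' Skin-temperature signal-quality series
#'
#' @param temp 2 Hz temperature series, degrees Celsius.
#' @param rules An [sqi_rules()] object.
#' @return Numeric SQI series in `[0, 1]`, aligned to the input.
#' @export
sqi_temp <- function(temp, rules = sqi_rules()) {
  n <- length(temp)
  if (n == 0) return(numeric(0))
  per_step <- 1 / rules$step_s
  score <- matrix(1, nrow = n, ncol = 2)
  score[temp < rules$temp_low, 1] <- rules$temp_low_score
  wf <- as.integer(round(rules$temp_flat_window_s * per_step))
  flat <- .trailing_flat(temp, wf, rules$temp_flat_eps)
  score[which(flat %in% TRUE), 2] <- rules$temp_flat_score
  apply(score, 1, min)
}

#' Session-level binary validity mask
#'
#' After a session completes, the mean and standard deviation of each
#' channel's SQI series are computed; a step is invalid (`0`) when either
#' channel's SQI falls below its session mean minus one standard
#' deviation, and valid (`1`) otherwise. Invalid steps are excluded from
#' event detection.
#'
#' @param sqi_eda Electrodermal SQI series.
#' @param sqi_temp Temperature SQI series, same length.
#' @return Integer series of 0/1.
#' @export
combine_sqi <- function(sqi_eda, sqi_temp) {
  if (length(sqi_eda) == 0) {
    abort("empty SQI series", class = "physioevents_domain_error")
  }
  stopifnot(length(sqi_eda) == length(sqi_temp))
  lo_e <- mean(sqi_eda) - sd(sqi_eda)
  lo_t <- mean(sqi_temp) - sd(sqi_temp)
  if (is.na(lo_e)) lo_e <- -Inf   # single-step session: sd undefined
  if (is.na(lo_t)) lo_t <- -Inf
  as.integer(!(sqi_eda < lo_e - .thr_eps | sqi_temp < lo_t - .thr_eps))
}

#' Compute the full signal-quality table for a cleaned session
#'
#' @param clean A `clean_signals` tibble from [preprocess()].
#' @param rules An [sqi_rules()] object.
#' @return An `sqi_series` tibble with columns `time_s`, `sqi_eda`,
#'   `sqi_temp`, `sqi_all`.
#' @export
compute_sqi <- function(clean, rules = sqi_rules()) {
  se <- sqi_eda(clean$eda_us, rules)
  st <- sqi_temp(clean$temp_c, rules)
  structure(tibble::tibble(time_s = clean$time_s, sqi_eda = se,
                           sqi_temp = st, sqi_all = combine_sqi(se, st)),
            class = c("sqi_series", class(tibble::tibble())))
}
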