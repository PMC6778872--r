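# Brute-force reference implementations, kept deliberately naive and
# independent of the package's vectorized code paths.

# rolling artifact flags: zero rule OR >3 SD from mean of preceding 1 s
oracle_flags <- function(x, t) {
  fs <- 1 / median(diff(t))
  w <- max(2, round(fs))
  n <- length(x)
  out <- x == 0
  for (i in seq_len(n)) {
    lo <- max(1, i - w)
    prev <- x[lo:(i - 1)]
    if (i >= 3 && length(prev) >= 2) {
      s <- sd(prev)
      if (s > 0 && abs(x[i] - mean(prev)) > 3 * s) out[i] <- TRUE
    }
  }
  out
}

# O(n * k) windowed-median replacement on unflagged neighbours
oracle_median_interp <- function(x, mask, order) {
  if (order %% 2 == 0) order <- order + 1
  half <- order %/% 2
  y <- x
  n <- length(x)
  for (i in which(mask)) {
    win <- max(1, i - half):min(n, i + half)
    good <- win[!mask[win]]
    if (length(good) > 0) {
      y[i] <- median(x[good])
    } else {
      good_all <- which(!mask)
      y[i] <- x[good_all[which.min(abs(good_all - i))]]
    }
  }
  y
}

# per-window mean with time-delimited non-overlapping windows
oracle_movavg <- function(x, fs, window_s) {
  n_out <- floor(length(x) / (fs * window_s) + 1e-9)
  vapply(seq_len(n_out), function(k) {
    idx <- which(floor(((seq_along(x)) - 1) / (fs * window_s) + 1e-9) == k - 1)
    mean(x[idx])
  }, numeric(1))
}

# trailing-window minimum scan for the EDR rise
oracle_edr <- function(eda, t_edr, a_edr, step_s = 0.5) {
  n <- length(eda)
  w <- round(t_edr / step_s)
  rise <- vapply(seq_len(n), function(i) {
    eda[i] - min(eda[max(1, i - w):i])
  }, numeric(1))
  ifelse(rise >= a_edr - 1e-9, rise, 0)
}

# trailing-window range for the temperature trend
oracle_temp_range <- function(temp, t_temp, dt_min, step_s = 0.5) {
  n <- length(temp)
  w <- round(t_temp / step_s)
  rng <- vapply(seq_len(n), function(i) {
    win <- temp[max(1, i - w):i]
    max(win) - min(win)
  }, numeric(1))
  ifelse(rng >= dt_min - 1e-9, rng, 0)
}

# direct two-stage one-Euro recursion (published formulation)
oracle_one_euro <- function(x, rate, mincutoff, beta, dcutoff) {
  al <- function(cutoff) {
    tau <- 1 / (2 * pi * cutoff)
    1 / (1 + tau * rate)
  }
  y <- numeric(length(x))
  y[1] <- x[1]
  dxh <- 0
  for (k in seq_along(x)[-1]) {
    dx <- (x[k] - y[k - 1]) * rate
    dxh <- al(dcutoff) * dx + (1 - al(dcutoff)) * dxh
    a <- al(mincutoff + beta * abs(dxh))
    y[k] <- a * x[k] + (1 - a) * y[k - 1]
  }
  y
}

# natural cubic smoothing spline at the knots via the Green & Silverman
# band matrices: minimize p ||y - f||^2 + (1 - p) f' K f, K = Q R^-1 Q^T
oracle_csaps_fit <- function(x, t, p) {
  n <- length(x)
  h <- diff(t)
  Q <- matrix(0, n, n - 2)
  R <- matrix(0, n - 2, n - 2)
  for (j in 2:(n - 1)) {
    Q[j - 1, j - 1] <- 1 / h[j - 1]
    Q[j, j - 1] <- -1 / h[j - 1] - 1 / h[j]
    Q[j + 1, j - 1] <- 1 / h[j]
    R[j - 1, j - 1] <- (h[j - 1] + h[j]) / 3
    if (j < n - 1) {
      R[j - 1, j] <- h[j] / 6
      R[j, j - 1] <- h[j] / 6
    }
  }
  K <- Q %*% solve(R) %*% t(Q)
  solve(p * diag(n) + (1 - p) * K, p * x)
}

# exhaustive best-subset selection under a separation constraint
oracle_best_subset <- function(times, scores, n_max, min_sep) {
  cand <- which(scores > 0)
  best <- numeric(0)
  best_sum <- -Inf
  for (k in seq_len(min(n_max, length(cand)))) {
    subsets <- utils::combn(cand, k, simplify = FALSE)
    for (ss in subsets) {
      tt <- times[ss]
      if (length(tt) > 1 && min(diff(sort(tt))) < min_sep) next
      if (sum(scores[ss]) > best_sum) {
        best_sum <- sum(scores[ss])
        best <- sort(tt)
      }
    }
  }
  best
}

# a plain 2 Hz series wrapped as clean_signals for detector-level tests
make_clean <- function(t2, eda = NULL, temp = NULL, hr = NULL) {
  n <- length(t2)
  structure(tibble::tibble(
    time_s = t2,
    eda_us = if (is.null(eda)) rep(4, n) else eda,
    temp_c = if (is.null(temp)) rep(33, n) else temp,
    hr_bpm = if (is.null(hr)) rep(72, n) else hr),
    fs = 2, session_id = "test",
    class = c("clean_signals", class(tibble::tibble())))
}
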