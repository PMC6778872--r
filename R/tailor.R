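#' Match detected events against annotations
#'
#' An event is a true positive when a `significant` annotation lies within
#' `tol_s` seconds of its time; each annotation matches at most one event,
#' with closer pairs matched first (ties toward the earlier event). All
#' other events are false positives. Precision is `TP / (TP + FP)`,
#' defined as 1 when no events were presented. Significant annotations
#' left unmatched are reported as missed moments.
#'
#' @param events An [event_table()].
#' @param annotations An [annotation_set()].
#' @param tol_s Matching tolerance, seconds (default 10, the clip
#'   half-width).
#' @return An `event_evaluation` list with elements `tp`, `fp`,
#'   `precision`, `matches` (tibble event_time_s/annotation_time_s) and
#'   `missed` (times of unmatched significant annotations).
#' @export
evaluate_events <- function(events, annotations, tol_s = 10) {
  stopifnot(tol_s > 0)
  sig <- annotations$time_s[annotations$label == "significant"]
  ev <- events$time_s
  pairs <- tidyr::expand_grid(ei = seq_along(ev), ai = seq_along(sig))
  if (nrow(pairs) > 0) {
    pairs$dist <- abs(ev[pairs$ei] - sig[pairs$ai])
    pairs <- pairs[pairs$dist <= tol_s + .thr_eps, , drop = FALSE]
    pairs <- pairs[order(pairs$dist, ev[pairs$ei]), , drop = FALSE]
  }
  used_e <- logical(length(ev)); used_a <- logical(length(sig))
  me <- integer(0); ma <- integer(0)
  for (r in seq_len(nrow(pairs))) {
    ei <- pairs$ei[r]; ai <- pairs$ai[r]
    if (!used_e[ei] && !used_a[ai]) {
      used_e[ei] <- TRUE; used_a[ai] <- TRUE
      me <- c(me, ei); ma <- c(ma, ai)
    }
  }
  tp <- sum(used_e); fp <- length(ev) - tp
  structure(list(
    tp = tp, fp = fp,
    precision = if (length(ev) == 0) 1 else tp / (tp + fp),
    matches = tibble::tibble(event_time_s = ev[me],
                             annotation_time_s = sig[ma]),
    missed = sort(sig[!used_a])),
    class = "event_evaluation")
}

#' @export
print.event_evaluation <- function(x, ...) {
  cat(sprintf("<event_evaluation> TP = %d, FP = %d, precision = %.3f, missed = %d\n",
              x$tp, x$fp, x$precision, length(x$missed)))
  invisible(x)
}

#' Candidate grid for parameter tailoring
#'
#' Candidate value lists searched by [fit_from_annotations()] and the
#' neighbourhood stepped through by [iterate_feedback()]. Threshold lists
#' are augmented at fit time with values seeded from the annotated
#' epochs' observed feature magnitudes, plus `Inf` ("channel off").
#'
#' @param a_edr,dt_min,min_peak_prominence Numeric candidate vectors for
#'   the three modality thresholds.
#' @param t_edr,t_temp Window-length candidates, seconds.
#' @param weights List of length-3 numeric vectors `(eda, temp, hr)`.
#' @param match_tolerance_s Event/annotation matching tolerance, seconds.
#' @return A `tailor_grid` list.
#' @export
tailor_grid <- function(a_edr = c(0.05, 0.1, 0.2, 0.4),
                        dt_min = c(0.01, 0.02, 0.05, 0.1),
                        min_peak_prominence = c(10, 15, 20, 25),
                        t_edr = 10, t_temp = 10,
                        weights = list(c(1, 1, 1), c(1, 0, 0),
                                       c(0, 1, 0), c(0, 0, 1)),
                        match_tolerance_s = 10) {
  g <- list(a_edr = a_edr, dt_min = dt_min,
            min_peak_prominence = min_peak_prominence,
            t_edr = t_edr, t_temp = t_temp, weights = weights,
            match_tolerance_s = match_tolerance_s)
  if (any(lengths(g[c("a_edr", "dt_min", "min_peak_prominence",
                      "t_edr", "t_temp", "weights")]) == 0)) {
    abort("grid candidate lists must be non-empty",
          class = "physioevents_validation_error")
  }
  if (g$match_tolerance_s <= 0) {
    abort("match_tolerance_s must be positive",
          class = "physioevents_validation_error")
  }
  structure(g, class = "tailor_grid")
}

## feature magnitudes inside +/- half_s epochs around each time; computed
## on threshold-free feature series so observed magnitudes can seed grids
.epoch_magnitudes <- function(clean, times, params, half_s = 5) {
  p0 <- params
  p0$a_edr <- 0; p0$dt_min <- 0; p0$min_peak_prominence <- 0
  feats <- detect_features(clean, do.call(detector_params, p0[names(p0) != "class"]))
  purrr::map_dfr(times, function(tt) {
    inwin <- feats$time_s >= tt - half_s & feats$time_s <= tt + half_s
    tibble::tibble(time_s = tt,
                   edr = if (any(inwin)) max(feats$edr[inwin]) else 0,
                   dtemp = if (any(inwin)) max(feats$dtemp[inwin]) else 0,
                   hrvar = if (any(inwin)) max(feats$hrvar[inwin]) else 0)
  })
}

## deterministic candidate table: defaults first, then grid x weights;
## `include_off` appends Inf ("channel off") to each threshold list
.candidate_table <- function(grid, seeds, defaults, include_off = TRUE) {
  uniq <- function(v) sort(unique(signif(v[is.finite(v) & v > 0], 6)))
  off <- if (include_off) Inf else numeric(0)
  cand <- tidyr::expand_grid(
    t_edr = sort(unique(grid$t_edr)),
    t_temp = sort(unique(grid$t_temp)),
    a_edr = c(uniq(c(grid$a_edr, seeds$a_edr)), off),
    dt_min = c(uniq(c(grid$dt_min, seeds$dt_min)), off),
    min_peak_prominence = c(uniq(c(grid$min_peak_prominence,
                                   seeds$min_peak_prominence)), off),
    wi = seq_along(grid$weights))
  first <- tibble::tibble(t_edr = defaults$t_edr, t_temp = defaults$t_temp,
                          a_edr = defaults$a_edr, dt_min = defaults$dt_min,
                          min_peak_prominence = defaults$min_peak_prominence,
                          wi = 0L)
  list(table = dplyr::bind_rows(first, cand),
       weights = c(list(c(defaults$weight_eda, defaults$weight_temp,
                          defaults$weight_hr)), grid$weights))
}

## lean internals used by the grid search: plain vectors, no tibbles

## greedy top-n selection; returns indices into `times`
.select_idx <- function(times, score, valid, n_max, min_sep_s) {
  cand <- which(score > 0 & valid)
  chosen <- integer(0)
  if (length(cand) > 0 && n_max > 0) {
    ord <- cand[order(-score[cand], times[cand])]
    for (i in ord) {
      if (length(chosen) >= n_max) break
      if (all(abs(times[i] - times[chosen]) >= min_sep_s)) {
        chosen <- c(chosen, i)
      }
    }
  }
  sort(chosen)
}

## nearest-first greedy matching; returns c(tp, fp)
.match_counts <- function(ev_times, sig_times, tol_s) {
  ne <- length(ev_times)
  if (ne == 0 || length(sig_times) == 0) return(c(0L, ne))
  d <- abs(outer(ev_times, sig_times, "-"))
  used_e <- logical(ne); used_a <- logical(length(sig_times))
  ord <- order(d)
  tp <- 0L
  for (k in ord) {
    if (d[k] > tol_s + .thr_eps) break
    ei <- (k - 1L) %% ne + 1L
    ai <- (k - 1L) %/% ne + 1L
    if (!used_e[ei] && !used_a[ai]) {
      used_e[ei] <- TRUE; used_a[ai] <- TRUE; tp <- tp + 1L
    }
  }
  c(tp, ne - tp)
}

#' Fit per-individual detector parameters from annotated recordings
#'
#' Stage-one tailoring: the three feature magnitudes are measured in
#' +/-5-second epochs around each significant annotation and used to seed
#' candidate thresholds; a deterministic grid search over thresholds,
#' windows and weight sets then retains the parameter set maximizing
#' precision (at the fixed per-session event cap) against the
#' annotations. The default parameter set is always evaluated first, so
#' the fit never scores below the defaults when they are in the grid.
#'
#' @param clean A `clean_signals` tibble from [preprocess()].
#' @param sqi An `sqi_series` tibble from [compute_sqi()], or `NULL`.
#' @param annotations An [annotation_set()] with at least one significant
#'   annotation.
#' @param grid A [tailor_grid()].
#' @param params Baseline [detector_params()] supplying defaults, the
#'   event cap and selection geometry.
#' @param seed_candidates If `TRUE` (default), augment the grid's
#'   threshold lists with the observed epoch magnitudes (the analogue of
#'   replacing default parameters with the values measured around each
#'   annotated moment); `FALSE` searches the supplied grid verbatim.
#' @return A `tailored_params` list with elements `params` (the fitted
#'   [detector_params()]), `precision`, `tp`, `fp`, `n_candidates` and
#'   `epochs` (the seeded epoch magnitudes).
#' @export
fit_from_annotations <- function(clean, sqi = NULL, annotations,
                                 grid = tailor_grid(),
                                 params = detector_params(),
                                 seed_candidates = TRUE) {
  sig <- annotations$time_s[annotations$label == "significant"]
  if (length(sig) == 0) {
    abort("tailoring needs at least one significant annotation",
          class = "physioevents_validation_error")
  }
  ep <- .epoch_magnitudes(clean, sig, unclass(params))
  seeds <- if (seed_candidates) {
    list(a_edr = ep$edr, dt_min = ep$dtemp, min_peak_prominence = ep$hrvar)
  } else {
    list(a_edr = numeric(0), dt_min = numeric(0),
         min_peak_prominence = numeric(0))
  }
  cands <- .candidate_table(grid, seeds, params,
                            include_off = seed_candidates)
  sqi_all <- if (is.null(sqi)) NULL else sqi$sqi_all
  span <- range(clean$time_s)

  ## threshold-free base features per (t_edr, t_temp) pair, computed once
  base_cache <- list()
  base_for <- function(te, tt) {
    key <- paste(te, tt)
    if (is.null(base_cache[[key]])) {
      p0 <- unclass(params)
      p0$t_edr <- te; p0$t_temp <- tt
      p0$a_edr <- 0; p0$dt_min <- 0; p0$min_peak_prominence <- 0
      base_cache[[key]] <<- detect_features(clean, do.call(detector_params, p0))
    }
    base_cache[[key]]
  }

  best <- NULL
  tab <- cands$table
  ## a zero-weight channel makes its threshold irrelevant: canonicalize to
  ## Inf and drop duplicate effective candidates (first occurrence kept)
  wmat <- do.call(rbind, cands$weights)[tab$wi + 1L, , drop = FALSE]
  eff <- tab
  eff$a_edr[wmat[, 1] == 0] <- Inf
  eff$dt_min[wmat[, 2] == 0] <- Inf
  eff$min_peak_prominence[wmat[, 3] == 0] <- Inf
  keep_rows <- which(!duplicated(cbind(eff, wmat)))

  valid <- if (is.null(sqi_all)) rep(TRUE, nrow(clean)) else sqi_all == 1
  sig_sorted <- sort(sig)
  for (r in keep_rows) {
    base <- base_for(tab$t_edr[r], tab$t_temp[r])
    wts <- cands$weights[[tab$wi[r] + 1L]]
    f1 <- ifelse(base$edr >= tab$a_edr[r] - .thr_eps, base$edr, 0)
    f2 <- ifelse(base$dtemp >= tab$dt_min[r] - .thr_eps, base$dtemp, 0)
    f3 <- ifelse(base$hrvar >= tab$min_peak_prominence[r] - .thr_eps,
                 base$hrvar, 0)
    s <- wts[1] * f1 + wts[2] * f2 + wts[3] * f3
    idx <- .select_idx(base$time_s, s, valid, params$max_events,
                       params$min_sep_s)
    cnt <- .match_counts(base$time_s[idx], sig_sorted,
                         grid$match_tolerance_s)
    evaln <- list(precision = if (length(idx) == 0) 1 else
                    cnt[1] / (cnt[1] + cnt[2]),
                  tp = cnt[1], fp = cnt[2])
    ## primary: precision; secondary: true positives; then prefer the most
    ## specific (largest finite) thresholds, mirroring the replacement of
    ## defaults by observed epoch magnitudes; finally earliest candidate
    spec_key <- sum(pmin(c(tab$a_edr[r] / max(tab$a_edr[is.finite(tab$a_edr)]),
                           tab$dt_min[r] / max(tab$dt_min[is.finite(tab$dt_min)]),
                           tab$min_peak_prominence[r] /
                             max(tab$min_peak_prominence[is.finite(tab$min_peak_prominence)])),
                         1))
    key <- c(evaln$precision, evaln$tp, spec_key)
    if (is.null(best) || key[1] > best$key[1] + .thr_eps ||
        (abs(key[1] - best$key[1]) <= .thr_eps &&
         (key[2] > best$key[2] ||
          (key[2] == best$key[2] && key[3] > best$key[3] + .thr_eps)))) {
      best <- list(row = r, key = key, evaln = evaln)
    }
  }
  r <- best$row
  wts <- cands$weights[[tab$wi[r] + 1L]]
  fitted <- params
  fitted$t_edr <- tab$t_edr[r]; fitted$t_temp <- tab$t_temp[r]
  fitted$a_edr <- tab$a_edr[r]; fitted$dt_min <- tab$dt_min[r]
  fitted$min_peak_prominence <- tab$min_peak_prominence[r]
  fitted$weight_eda <- wts[1]; fitted$weight_temp <- wts[2]
  fitted$weight_hr <- wts[3]
  final <- evaluate_events(
    run_detector(clean, if (is.null(sqi_all)) NULL else
      tibble::tibble(sqi_all = sqi_all), fitted),
    annotations, grid$match_tolerance_s)
  structure(list(params = fitted, precision = final$precision,
                 tp = final$tp, fp = final$fp, missed = final$missed,
                 n_candidates = length(keep_rows), epochs = ep),
            class = "tailored_params")
}

#' @export
print.tailored_params <- function(x, ...) {
  cat(sprintf("<tailored_params> precision = %.3f (TP %d / FP %d) over %d candidates\n",
              x$precision, x$tp, x$fp, x$n_candidates))
  print(x$params)
  invisible(x)
}

## nearest grid values around v in sorted candidate list (one step each way)
.grid_neighbours <- function(v, cands) {
  cands <- sort(unique(c(cands, v)))
  i <- which.min(abs(cands - v))
  unique(cands[pmax(1, i - 1):pmin(length(cands), i + 1)])
}

#' Adjust parameters from true/false-positive feedback
#'
#' Stage-two tailoring: given verdicts on previously detected events
#' (true or false positive) and any reported missed moments, performs a
#' local search over the grid neighbourhood of the current parameters
#' (one grid step per field, one field at a time, plus the weight sets).
#' Each candidate re-runs the detector; the objective is the margin
#' (true positives retained) - (false positives retained) +
#' (missed moments recovered), where an event time counts as retained or
#' recovered when a detection falls within the matching tolerance of it.
#' Ties keep the current parameters, so all-true-positive feedback with
#' nothing missed leaves the parameters unchanged.
#'
#' @param params Current [detector_params()].
#' @param clean A `clean_signals` tibble.
#' @param sqi An `sqi_series` tibble or `NULL`.
#' @param feedback A data frame with columns `time_s` and `verdict`
#'   (`"TP"` or `"FP"`), one row per presented event.
#' @param missed Numeric vector of reported missed significant times
#'   (default none).
#' @param grid A [tailor_grid()] defining the neighbourhood.
#' @return A `tailored_params` list (precision here is the margin
#'   objective scaled to `[0, 1]` by the number of feedback items).
#' @export
iterate_feedback <- function(params, clean, sqi = NULL, feedback,
                             missed = numeric(0), grid = tailor_grid()) {
  if (is.null(feedback) || nrow(feedback) == 0) {
    abort("feedback must contain at least one verdict",
          class = "physioevents_validation_error")
  }
  bad <- setdiff(unique(feedback$verdict), c("TP", "FP"))
  if (length(bad) > 0) {
    abort(paste0("unknown verdict(s): ", paste(bad, collapse = ", ")),
          class = "physioevents_validation_error")
  }
  tol <- grid$match_tolerance_s
  tp_times <- feedback$time_s[feedback$verdict == "TP"]
  fp_times <- feedback$time_s[feedback$verdict == "FP"]

  hits_near <- function(ev, times) {
    if (nrow(ev) == 0) return(rep(FALSE, length(times)))
    vapply(times, function(tt) any(abs(ev$time_s - tt) <= tol + .thr_eps),
           logical(1))
  }
  margin <- function(ev) {
    tp_ret <- if (length(tp_times)) sum(hits_near(ev, tp_times)) else 0
    fp_ret <- if (length(fp_times)) sum(hits_near(ev, fp_times)) else 0
    miss_rec <- if (length(missed)) sum(hits_near(ev, missed)) else 0
    tp_ret - fp_ret + miss_rec
  }

  ## candidate list: current params first, then one-field grid steps
  cands <- list(params)
  for (field in c("a_edr", "dt_min", "min_peak_prominence", "t_edr", "t_temp")) {
    for (v in .grid_neighbours(params[[field]], grid[[field]])) {
      if (v != params[[field]]) {
        p <- params; p[[field]] <- v
        cands[[length(cands) + 1L]] <- p
      }
    }
  }
  cur_w <- c(params$weight_eda, params$weight_temp, params$weight_hr)
  for (w in grid$weights) {
    if (!isTRUE(all.equal(w, cur_w))) {
      p <- params
      p$weight_eda <- w[1]; p$weight_temp <- w[2]; p$weight_hr <- w[3]
      cands[[length(cands) + 1L]] <- p
    }
  }

  best_i <- 1L
  best_m <- -Inf
  for (i in seq_along(cands)) {
    ev <- run_detector(clean, sqi, cands[[i]])
    m <- margin(ev)
    if (m > best_m) { best_m <- m; best_i <- i }   # strict: ties keep earlier
  }
  denom <- nrow(feedback) + length(missed)
  structure(list(params = cands[[best_i]],
                 precision = (best_m + length(fp_times)) / denom,
                 tp = NA_integer_, fp = NA_integer_, missed = missed,
                 n_candidates = length(cands), epochs = NULL),
            class = "tailored_params")
}

#' Read event feedback from CSV (`time_s,verdict`)
#'
#' Verdicts are `"TP"`, `"FP"`, or `"missed"` (a significant moment the
#' detector did not present; its time is returned separately).
#'
#' @param path CSV path.
#' @return List with `feedback` (tibble `time_s`, `verdict` of TP/FP) and
#'   `missed` (numeric times).
#' @export
read_feedback <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("no such file: ", path), class = "physioevents_io_error")
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("time_s", "verdict") %in% names(df))) {
    abort("feedback needs columns time_s and verdict",
          class = "physioevents_format_error")
  }
  list(feedback = tibble::as_tibble(df[df$verdict %in% c("TP", "FP"), ]),
       missed = df$time_s[df$verdict == "missed"])
}
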