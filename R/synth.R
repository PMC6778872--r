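#' Configuration for a synthetic three-channel session
#'
#' Describes a 15 Hz recording with per-channel baselines, white Gaussian
#' noise, slow sinusoidal drift, embedded salient events and injected
#' sensor artifacts. Event morphologies are idealized so that each
#' detector measures the embedded magnitude exactly at zero noise: an
#' electrodermal reaction is a linear ramp of `magnitude` microsiemens
#' over `duration_s` seconds followed by exponential recovery; a
#' temperature event is a monotone excursion of `magnitude` degrees
#' Celsius over `duration_s` with slow relaxation; a heart-rate event is
#' a triangular excursion of prominence `magnitude` bpm.
#'
#' @param duration_s Session length, seconds.
#' @param fs Sampling rate, Hz (nominal 15).
#' @param baseline_eda Baseline skin conductance, microsiemens.
#' @param baseline_temp Baseline fingertip temperature, degrees Celsius.
#' @param baseline_hr Baseline heart rate, bpm.
#' @param noise_eda,noise_temp,noise_hr White-noise standard deviations.
#' @param drift_amp_eda,drift_amp_temp,drift_amp_hr Amplitudes of a slow
#'   (300-second period) sinusoidal drift per channel.
#' @param events Data frame with columns `time_s` (event onset),
#'   `modality` (`"eda"`, `"temp"`, `"hr"`), `magnitude`, `duration_s`,
#'   and optionally `direction` (+1 or -1, default +1): heart-rate and
#'   temperature excursions may point either way (acceleration vs
#'   deceleration, warming vs cooling), electrodermal reactions are
#'   always rises. Interleaving accelerations and decelerations matters
#'   for realistic heart-rate sessions: between two same-direction
#'   excursions, the deepest point of the return to baseline itself
#'   carries excursion-scale topographic prominence.
#' @param distractors Data frame with the same columns as `events`:
#'   transients injected into the signal but *not* annotated, emulating
#'   sub-salient physiological activity that an untailored detector may
#'   mistake for events.
#' @param artifacts Data frame with columns `time_s`, `kind`
#'   (`"zero_dropout"`, `"spike"`, `"flatline"`, `"out_of_range"`),
#'   `duration_s` and optionally `channel` (default `"eda"`).
#' @param seed Integer seed fixing the full realization.
#' @return A `synth_config` list.
#' @export
synth_config <- function(duration_s = 300, fs = 15,
                         baseline_eda = 4, baseline_temp = 33,
                         baseline_hr = 72,
                         noise_eda = 0.005, noise_temp = 0.002,
                         noise_hr = 0.5,
                         drift_amp_eda = 0.02, drift_amp_temp = 0.05,
                         drift_amp_hr = 1,
                         events = NULL, distractors = NULL,
                         artifacts = NULL, seed = 1L) {
  empty_events <- tibble::tibble(time_s = double(), modality = character(),
                                 magnitude = double(), duration_s = double(),
                                 direction = double())
  as_events <- function(x) {
    if (is.null(x)) return(empty_events)
    x <- tibble::as_tibble(x)
    if (!"direction" %in% names(x)) x$direction <- 1
    if (any(!x$direction %in% c(-1, 1))) {
      abort("event direction must be +1 or -1",
            class = "physioevents_validation_error")
    }
    x
  }
  events <- as_events(events)
  distractors <- as_events(distractors)
  artifacts <- if (is.null(artifacts)) {
    tibble::tibble(time_s = double(), kind = character(),
                   duration_s = double(), channel = character())
  } else {
    a <- tibble::as_tibble(artifacts)
    if (!"channel" %in% names(a)) a$channel <- "eda"
    a
  }
  all_ev <- dplyr::bind_rows(events, distractors)
  if (nrow(all_ev) > 0) {
    if (any(all_ev$magnitude < 0)) {
      abort("event magnitudes must be non-negative",
            class = "physioevents_validation_error")
    }
    if (any(all_ev$time_s < 0 |
            all_ev$time_s + all_ev$duration_s > duration_s)) {
      abort("events must lie within the session duration",
            class = "physioevents_validation_error")
    }
    ## overlapping same-modality transients would superpose ambiguously
    ov <- all_ev |>
      dplyr::arrange(.data$modality, .data$time_s) |>
      dplyr::group_by(.data$modality) |>
      dplyr::mutate(overlap = .data$time_s <
                      dplyr::lag(.data$time_s + .data$duration_s,
                                 default = -Inf)) |>
      dplyr::ungroup()
    if (any(ov$overlap)) {
      abort("overlapping events of the same modality",
            class = "physioevents_validation_error")
    }
  }
  if (nrow(artifacts) > 0 &&
      any(artifacts$time_s < 0 |
          artifacts$time_s + artifacts$duration_s > duration_s)) {
    abort("artifacts must lie within the session duration",
          class = "physioevents_validation_error")
  }
  structure(list(duration_s = duration_s, fs = fs,
                 baseline_eda = baseline_eda, baseline_temp = baseline_temp,
                 baseline_hr = baseline_hr,
                 noise_eda = noise_eda, noise_temp = noise_temp,
                 noise_hr = noise_hr,
                 drift_amp_eda = drift_amp_eda,
                 drift_amp_temp = drift_amp_temp,
                 drift_amp_hr = drift_amp_hr,
                 events = events, distractors = distractors,
                 artifacts = artifacts, seed = as.integer(seed)),
            class = "synth_config")
}

## event shape templates on a time axis t (seconds), zero outside support
.shape_edr <- function(t, onset, magnitude, duration) {
  y <- numeric(length(t))
  ramp <- t >= onset & t < onset + duration
  y[ramp] <- magnitude * (t[ramp] - onset) / duration
  rec <- t >= onset + duration
  y[rec] <- magnitude * exp(-(t[rec] - onset - duration) / duration)
  y
}

.shape_temp <- function(t, onset, magnitude, duration) {
  y <- numeric(length(t))
  ramp <- t >= onset & t < onset + duration
  ## smooth monotone rise (half-cosine) of `magnitude` over `duration`
  y[ramp] <- magnitude * 0.5 * (1 - cos(pi * (t[ramp] - onset) / duration))
  rec <- t >= onset + duration
  y[rec] <- magnitude * exp(-(t[rec] - onset - duration) / (4 * duration))
  y
}

.shape_hr <- function(t, onset, magnitude, duration) {
  y <- numeric(length(t))
  half <- duration / 2
  up <- t >= onset & t < onset + half
  y[up] <- magnitude * (t[up] - onset) / half
  dn <- t >= onset + half & t <= onset + duration
  y[dn] <- magnitude * (1 - (t[dn] - onset - half) / half)
  y
}

#' Generate a synthetic session with known ground truth
#'
#' Builds the 15 Hz three-channel recording described by the
#' configuration and the matching annotation set, with one `significant`
#' annotation at each embedded event's feature-maximal time (ramp end for
#' electrodermal and temperature events, apex for heart-rate events).
#' Fully reproducible: the same configuration and seed give bit-identical
#' output.
#'
#' @param cfg A [synth_config()].
#' @return List with elements `recording` (a [physio_recording()]) and
#'   `annotations` (an [annotation_set()]).
#' @export
generate_session <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  withr::with_seed(cfg$seed, {
    n <- as.integer(round(cfg$duration_s * cfg$fs))
    t <- (seq_len(n) - 1) / cfg$fs
    drift <- function(amp, phase) amp * sin(2 * pi * t / 300 + phase)
    eda <- cfg$baseline_eda + drift(cfg$drift_amp_eda, 0) +
      rnorm(n, 0, cfg$noise_eda)
    temp <- cfg$baseline_temp + drift(cfg$drift_amp_temp, pi / 3) +
      rnorm(n, 0, cfg$noise_temp)
    hr <- cfg$baseline_hr + drift(cfg$drift_amp_hr, 2 * pi / 3) +
      rnorm(n, 0, cfg$noise_hr)

    ann_time <- numeric(0); ann_note <- character(0)
    inject <- function(ev, annotate) {
      for (i in seq_len(nrow(ev))) {
        on <- ev$time_s[i]; mag <- ev$magnitude[i]; du <- ev$duration_s[i]
        dir <- ev$direction[i]
        peak_t <- switch(ev$modality[i],
          eda = { eda <<- eda + .shape_edr(t, on, mag, du); on + du },
          temp = { temp <<- temp + dir * .shape_temp(t, on, mag, du)
                   on + du },
          hr = { hr <<- hr + dir * .shape_hr(t, on, mag, du); on + du / 2 },
          abort(paste0("unknown modality: ", ev$modality[i]),
                class = "physioevents_validation_error"))
        if (annotate) {
          ann_time <<- c(ann_time, peak_t)
          ann_note <<- c(ann_note, paste0(ev$modality[i], " magnitude ", mag))
        }
      }
    }
    inject(cfg$events, annotate = TRUE)
    inject(cfg$distractors, annotate = FALSE)

    af <- cfg$artifacts
    for (i in seq_len(nrow(af))) {
      idx <- which(t >= af$time_s[i] & t < af$time_s[i] + af$duration_s[i])
      if (length(idx) == 0) next
      ch <- af$channel[i]
      cur <- switch(ch, eda = eda, temp = temp, hr = hr,
                    abort(paste0("unknown channel: ", ch),
                          class = "physioevents_validation_error"))
      cur[idx] <- switch(af$kind[i],
        zero_dropout = 0,
        spike = cur[idx] + switch(ch, eda = 50, temp = 20, hr = 120),
        flatline = cur[max(idx[1] - 1, 1)],
        out_of_range = switch(ch, eda = 35, temp = 10, hr = 250),
        abort(paste0("unknown artifact kind: ", af$kind[i]),
              class = "physioevents_validation_error"))
      switch(ch, eda = { eda <- cur }, temp = { temp <- cur },
             hr = { hr <- cur })
    }

    rec <- physio_recording(
      tibble::tibble(time_s = t, eda_us = eda, temp_c = temp, hr_bpm = hr),
      session_id = paste0("synth-seed", cfg$seed), fs = cfg$fs)
    ord <- order(ann_time)
    ann <- annotation_set(tibble::tibble(
      time_s = ann_time[ord],
      label = rep("significant", length(ann_time)),
      note = ann_note[ord]))
    list(recording = rec, annotations = ann)
  })
}

#' Canned sessions emulating distinct responder profiles
#'
#' Three mono-modal session archetypes whose event magnitudes sit near
#' individually tailored thresholds typical of wearable autonomic-signal
#' detection: `"eda_responder"` (sharp electrodermal ramps of 0.24 uS in
#' 10 s), `"hr_responder"` (heart-rate excursions of 30 bpm prominence),
#' and `"temp_responder"` (temperature excursions of about 0.02 degC over
#' 25 s). Each session also embeds weaker unannotated distractor
#' transients in the same modality — strong enough to fool the default
#' thresholds but below the annotated events — so that tailoring has
#' false positives to suppress.
#'
#' @param kind One of `"eda_responder"`, `"hr_responder"`,
#'   `"temp_responder"`.
#' @param seed Integer seed.
#' @param duration_s Session length, seconds.
#' @param event_magnitude Override of the archetype's event magnitude.
#' @return As [generate_session()]: list of `recording` and
#'   `annotations`.
#' @export
reference_session <- function(kind = c("eda_responder", "hr_responder",
                                       "temp_responder"),
                              seed = 1L, duration_s = 360,
                              event_magnitude = NULL) {
  kind <- match.arg(kind)
  onsets <- seq(60, duration_s - 60, by = 75)
  mid <- head(onsets, -1) + 38       # distractors between events
  spec <- switch(kind,
    eda_responder = list(modality = "eda", magnitude = 0.24, duration = 10,
                         distractor = 0.12),
    hr_responder = list(modality = "hr", magnitude = 30, duration = 20,
                        distractor = 18),
    temp_responder = list(modality = "temp", magnitude = 0.02, duration = 25,
                          distractor = 0.012))
  if (!is.null(event_magnitude)) spec$magnitude <- event_magnitude
  ## heart-rate excursions alternate acceleration/deceleration (see
  ## synth_config); other modalities point one way
  ev_dir <- if (kind == "hr_responder") {
    rep_len(c(1, -1), length(onsets))
  } else rep(1, length(onsets))
  di_dir <- if (kind == "hr_responder") {
    rep_len(c(1, -1), length(mid))
  } else rep(1, length(mid))
  cfg <- synth_config(
    duration_s = duration_s, seed = seed,
    ## temperature drift is kept below the event scale so that trend
    ## excursions, not the session-long drift, carry the signal
    drift_amp_temp = if (kind == "temp_responder") 0.003 else 0.05,
    noise_temp = if (kind == "temp_responder") 0.001 else 0.002,
    events = tibble::tibble(time_s = onsets, modality = spec$modality,
                            magnitude = spec$magnitude,
                            duration_s = spec$duration, direction = ev_dir),
    distractors = tibble::tibble(time_s = mid, modality = spec$modality,
                                 magnitude = spec$distractor,
                                 duration_s = spec$duration,
                                 direction = di_dir))
  generate_session(cfg)
}
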