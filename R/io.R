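#' Construct a physiological session recording
#'
#' A recording is a tibble with one row per sample and columns `time_s`
#' (seconds from session start, strictly increasing), `eda_us`
#' (electrodermal activity, microsiemens), `temp_c` (skin temperature,
#' degrees Celsius) and `hr_bpm` (heart rate, beats per minute). The
#' sampling frequency (nominally 15 Hz for the fingertip sensor) and a
#' session identifier travel as attributes.
#'
#' @param data Data frame with columns `time_s`, `eda_us`, `temp_c`, `hr_bpm`.
#' @param session_id Character session label.
#' @param fs Sampling frequency in Hz. If `NULL`, inferred as
#'   `1 / median(diff(time_s))`; a warning is given if the inferred rate
#'   deviates from 15 Hz by more than 10%.
#' @return A `physio_recording` tibble.
#' @export
physio_recording <- function(data, session_id = "session", fs = NULL) {
  required <- c("time_s", "eda_us", "temp_c", "hr_bpm")
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("recording is missing column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "physioevents_format_error")
  }
  out <- tibble::as_tibble(data[required])
  if (nrow(out) == 0) {
    abort("recording has no samples", class = "physioevents_validation_error")
  }
  if (any(!is.finite(out$time_s)) || any(diff(out$time_s) <= 0)) {
    abort("time_s must be finite and strictly increasing",
          class = "physioevents_validation_error")
  }
  inferred <- if (nrow(out) >= 2) 1 / median(diff(out$time_s)) else NA_real_
  if (is.null(fs)) {
    fs <- inferred
    if (is.finite(fs) && abs(fs - 15) / 15 > 0.10) {
      warn(sprintf("inferred sampling rate %.3f Hz deviates from nominal 15 Hz by >10%%", fs))
    }
  }
  if (!is.finite(fs) || fs <= 0) {
    abort("fs must be a positive number", class = "physioevents_validation_error")
  }
  structure(out,
            session_id = session_id, fs = fs,
            class = c("physio_recording", class(tibble::tibble())))
}

#' Sampling frequency of a recording
#' @param rec A `physio_recording`.
#' @return Sampling frequency in Hz.
#' @export
recording_fs <- function(rec) attr(rec, "fs")

#' Read a session recording from CSV
#'
#' Expects a delimited text file with a header naming columns `time_s`,
#' `eda_us`, `temp_c` and `hr_bpm` (the on-disk dialect used throughout
#' this package; the sensor hardware itself defines no file format).
#'
#' @param path Path to a CSV file.
#' @param session_id Session label; defaults to the file name.
#' @return A [physio_recording()] tibble.
#' @export
read_recording <- function(path, session_id = NULL) {
  if (!file.exists(path)) {
    abort(paste0("no such file: ", path), class = "physioevents_io_error")
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  physio_recording(df, session_id = session_id %||%
                     tools::file_path_sans_ext(basename(path)))
}

#' Write a session recording to CSV
#' @param rec A `physio_recording`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  utils::write.csv(as.data.frame(rec), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Construct an annotation set
#'
#' Annotations mark session times judged significant (moments standing out
#' from the ordinary flow) or explicitly not significant; they drive the
#' per-individual tailoring of detector parameters.
#'
#' @param data Data frame with columns `time_s`, `label` and optionally
#'   `note`. Labels must be `"significant"` or `"not_significant"`.
#' @return An `annotation_set` tibble.
#' @export
annotation_set <- function(data) {
  if (!all(c("time_s", "label") %in% names(data))) {
    abort("annotations need columns time_s and label",
          class = "physioevents_format_error")
  }
  if (!"note" %in% names(data)) data$note <- ""
  out <- tibble::as_tibble(data[c("time_s", "label", "note")])
  bad <- setdiff(unique(out$label), c("significant", "not_significant"))
  if (length(bad) > 0) {
    abort(paste0("unknown annotation label(s): ", paste(bad, collapse = ", ")),
          class = "physioevents_validation_error")
  }
  structure(out, class = c("annotation_set", class(tibble::tibble())))
}

#' Read annotations from CSV (`time_s,label,note`)
#' @param path CSV path.
#' @return An [annotation_set()] tibble.
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("no such file: ", path), class = "physioevents_io_error")
  }
  annotation_set(utils::read.csv(path, stringsAsFactors = FALSE,
                                 colClasses = c(note = "character")))
}

#' Write annotations to CSV
#' @param ann An `annotation_set`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(ann, path) {
  utils::write.csv(as.data.frame(ann), path, row.names = FALSE)
  invisible(path)
}

#' Compute the video-clip window for an event
#'
#' Each detected event is associated with a clip spanning 10 seconds before
#' to 10 seconds after the event, truncated to the recording span, so an
#' interior event yields a 20-second clip and boundary events shorter ones.
#'
#' @param time_s Event time(s) in seconds (vectorized).
#' @param span Length-2 numeric, recording start and end in seconds.
#' @param halfwidth_s Clip half-width in seconds (default 10).
#' @return Tibble with columns `clip_start_s`, `clip_end_s`.
#' @export
clip_window <- function(time_s, span, halfwidth_s = 10) {
  if (any(time_s < span[1] - .thr_eps | time_s > span[2] + .thr_eps)) {
    abort("event time outside the recording span",
          class = "physioevents_domain_error")
  }
  tibble::tibble(clip_start_s = pmax(time_s - halfwidth_s, span[1]),
                 clip_end_s   = pmin(time_s + halfwidth_s, span[2]))
}

.event_cols <- c("time_s", "score", "dominant_modality",
                 "clip_start_s", "clip_end_s")

#' Assemble an event table
#' @param data Data frame with columns `time_s`, `score`,
#'   `dominant_modality`, `clip_start_s`, `clip_end_s`.
#' @return An `event_table` tibble with stable column order.
#' @export
event_table <- function(data = NULL) {
  if (is.null(data) || nrow(as.data.frame(data)) == 0) {
    out <- tibble::tibble(time_s = double(), score = double(),
                          dominant_modality = character(),
                          clip_start_s = double(), clip_end_s = double())
  } else {
    missing_cols <- setdiff(.event_cols, names(data))
    if (length(missing_cols) > 0) {
      abort(paste0("event table missing column(s): ",
                   paste(missing_cols, collapse = ", ")),
            class = "physioevents_format_error")
    }
    out <- tibble::as_tibble(data[.event_cols])
    bad <- out$clip_start_s > out$time_s + .thr_eps |
      out$time_s > out$clip_end_s + .thr_eps
    if (any(bad)) {
      abort("clip windows must contain their event time",
            class = "physioevents_validation_error")
    }
  }
  structure(out, class = c("event_table", class(tibble::tibble())))
}

#' Write detected events to CSV and JSON
#'
#' Writes a delimited text file at `path` and a JSON file alongside it
#' (same stem, `.json` extension), both carrying all event fields in a
#' stable column order.
#'
#' @param events An [event_table()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path) {
  events <- event_table(events)
  utils::write.csv(as.data.frame(events), path, row.names = FALSE, quote = FALSE)
  json_path <- paste0(tools::file_path_sans_ext(path), ".json")
  jsonlite::write_json(as.data.frame(events), json_path,
                       digits = NA, auto_unbox = FALSE)
  invisible(path)
}

#' Read events from CSV or JSON
#' @param path Path to a file written by [write_events()].
#' @return An [event_table()].
#' @export
read_events <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("no such file: ", path), class = "physioevents_io_error")
  }
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    df <- jsonlite::fromJSON(path)
    if (length(df) == 0) df <- NULL
  } else {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    if (nrow(df) == 0) df <- NULL
  }
  event_table(df)
}

#' Detector parameters
#'
#' The tunable thresholds and weights of the event detector, all
#' per-individual: `t_edr`/`a_edr` define an electrodermal reaction (a rise
#' of at least `a_edr` microsiemens within a trailing `t_edr`-second
#' window; canonically 0.05 uS in 10 s), `min_peak_prominence` the
#' heart-rate peak prominence threshold in bpm, `t_temp`/`dt_min` the
#' temperature trend test (max minus min over a trailing `t_temp`-second
#' window at least `dt_min` degrees Celsius), and `weight_eda`,
#' `weight_temp`, `weight_hr` the non-negative modality weights of the
#' combined salience score. `max_events` caps the events reported per
#' session and `min_sep_s` keeps selected events (and hence their
#' +/-`clip_halfwidth_s` clips) disjoint.
#'
#' @param t_edr Electrodermal-reaction search window, seconds.
#' @param a_edr Minimum electrodermal rise, microsiemens.
#' @param min_peak_prominence Heart-rate peak prominence threshold, bpm.
#' @param t_temp Temperature trend window, seconds.
#' @param dt_min Minimum temperature range over `t_temp`, degrees Celsius.
#' @param weight_eda,weight_temp,weight_hr Non-negative score weights.
#' @param max_events Maximum events per session.
#' @param min_sep_s Minimum separation between selected events, seconds.
#' @param clip_halfwidth_s Clip half-width, seconds.
#' @param temp_mode `"range"` (default) fires on the windowed range alone;
#'   `"reversal"` additionally requires a slope sign change in the window.
#' @return A `detector_params` list.
#' @export
detector_params <- function(t_edr = 10, a_edr = 0.05,
                            min_peak_prominence = 10,
                            t_temp = 10, dt_min = 0.01,
                            weight_eda = 1, weight_temp = 1, weight_hr = 1,
                            max_events = 5, min_sep_s = 20,
                            clip_halfwidth_s = 10,
                            temp_mode = c("range", "reversal")) {
  temp_mode <- match.arg(temp_mode)
  p <- list(t_edr = t_edr, a_edr = a_edr,
            min_peak_prominence = min_peak_prominence,
            t_temp = t_temp, dt_min = dt_min,
            weight_eda = weight_eda, weight_temp = weight_temp,
            weight_hr = weight_hr,
            max_events = max_events, min_sep_s = min_sep_s,
            clip_halfwidth_s = clip_halfwidth_s, temp_mode = temp_mode)
  if (p$t_edr <= 0 || p$t_temp <= 0 || p$min_sep_s < 0 ||
      p$clip_halfwidth_s <= 0) {
    abort("window lengths must be positive", class = "physioevents_validation_error")
  }
  thr <- c(p$a_edr, p$min_peak_prominence, p$dt_min)
  if (any(thr[is.finite(thr)] < 0)) {
    abort("thresholds must be non-negative", class = "physioevents_validation_error")
  }
  if (p$weight_eda < 0 || p$weight_temp < 0 || p$weight_hr < 0) {
    abort("weights must be non-negative", class = "physioevents_validation_error")
  }
  if (p$max_events < 0 || p$max_events != round(p$max_events)) {
    abort("max_events must be a non-negative integer",
          class = "physioevents_validation_error")
  }
  structure(p, class = "detector_params")
}

#' Read or write detector parameters as YAML
#'
#' The serialized field names mirror the per-individual parameter tables:
#' one threshold, window and weight per physiological modality.
#'
#' @param path YAML (or JSON) file path.
#' @return For `read_params`, a [detector_params()] object.
#' @export
read_params <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("no such file: ", path), class = "physioevents_io_error")
  }
  raw <- tryCatch(yaml::read_yaml(path), error = function(e) {
    abort(paste0("cannot parse parameter file: ", conditionMessage(e)),
          class = "physioevents_format_error")
  })
  if (!is.list(raw)) {
    abort("parameter file must contain a mapping",
          class = "physioevents_format_error")
  }
  known <- names(formals(detector_params))
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0) {
    abort(paste0("unknown parameter field(s): ", paste(unknown, collapse = ", ")),
          class = "physioevents_format_error")
  }
  do.call(detector_params, raw)
}

#' @rdname read_params
#' @param params A [detector_params()] object.
#' @export
write_params <- function(params, path) {
  stopifnot(inherits(params, "detector_params"))
  yaml::write_yaml(unclass(params), path)
  invisible(path)
}

#' @export
print.detector_params <- function(x, ...) {
  cat("<detector_params>\n")
  cat(sprintf("  EDR:  rise >= %g uS over %g s (weight %g)\n",
              x$a_edr, x$t_edr, x$weight_eda))
  cat(sprintf("  temp: range >= %g degC over %g s, mode %s (weight %g)\n",
              x$dt_min, x$t_temp, x$temp_mode, x$weight_temp))
  cat(sprintf("  HR:   peak prominence >= %g bpm (weight %g)\n",
              x$min_peak_prominence, x$weight_hr))
  cat(sprintf("  selection: top %d events, >= %g s apart, clips +/- %g s\n",
              x$max_events, x$min_sep_s, x$clip_halfwidth_s))
  invisible(x)
}
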