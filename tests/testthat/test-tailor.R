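mk_events <- function(times, score = 1) {
  event_table(tibble::tibble(
    time_s = times, score = score, dominant_modality = "eda",
    clip_start_s = times - 10, clip_end_s = times + 10))
}
mk_ann <- function(times, label = "significant") {
  annotation_set(tibble::tibble(time_s = times, label = label))
}

test_that("evaluation matches events to annotations nearest-first", {
  ev <- evaluate_events(mk_events(c(100, 200, 300)),
                        mk_ann(c(98, 205, 303)))
  expect_equal(glance(ev),
               tibble::tibble(tp = 3L, fp = 0L, precision = 1,
                              n_missed = 0L))

  # 10 events, 7 near annotations: precision 0.7
  ev2 <- evaluate_events(mk_events(seq(50, 500, by = 50)),
                         mk_ann(seq(50, 350, by = 50) + 3))
  expect_equal(ev2$precision, 0.7)
  expect_equal(ev2$tp + ev2$fp, 10)

  # one annotation equidistant between two events: earlier event wins
  ev3 <- evaluate_events(mk_events(c(95, 105)), mk_ann(100))
  expect_equal(ev3$tp, 1)
  expect_equal(ev3$fp, 1)
  expect_equal(tidy(ev3)$event_time_s, 95)

  # no events: precision defined as 1
  expect_equal(evaluate_events(mk_events(numeric(0)), mk_ann(100))$precision, 1)

  # each annotation matches at most one event
  ev4 <- evaluate_events(mk_events(c(100, 104)), mk_ann(c(101)))
  expect_equal(ev4$tp, 1)

  # precision is always in [0, 1] and counts add up
  withr::with_seed(13, {
    for (i in 1:10) {
      e <- mk_events(sort(runif(5, 0, 500)))
      a <- mk_ann(sort(runif(3, 0, 500)))
      g <- glance(evaluate_events(e, a))
      expect_gte(g$precision, 0)
      expect_lte(g$precision, 1)
      expect_equal(g$tp + g$fp, 5)
    }
  })
})

test_that("stage-one tailoring recovers an injected electrodermal threshold", {
  ses <- reference_session("eda_responder", seed = 101)
  clean <- preprocess(ses$recording)
  sqi <- compute_sqi(clean)
  fit <- fit_from_annotations(clean, sqi, ses$annotations)

  expect_equal(fit$precision, 1)
  expect_equal(fit$tp, 4)
  # recovered threshold sits in the same base-grid cell as the generating
  # 0.24 uS magnitude (i.e. within one grid step)
  base <- tailor_grid()$a_edr
  expect_equal(findInterval(fit$params$a_edr, base),
               findInterval(0.24, base))
  # the tailored detector is electrodermally dominated
  ev <- run_detector(clean, sqi, fit$params)
  expect_true(all(ev$dominant_modality == "eda"))
})

test_that("stage-one tailoring recovers heart-rate-dominated parameters", {
  ses <- reference_session("hr_responder", seed = 55)
  clean <- preprocess(ses$recording)
  sqi <- compute_sqi(clean)
  fit <- fit_from_annotations(clean, sqi, ses$annotations)
  expect_equal(fit$precision, 1)
  expect_equal(fit$tp, 4)
  ev <- run_detector(clean, sqi, fit$params)
  expect_true(all(ev$dominant_modality == "hr"))
  # threshold clears the strongest distractor but keeps every event
  expect_gt(fit$params$min_peak_prominence, 12)
})

test_that("tailoring with a defaults-only grid returns the defaults", {
  ses <- reference_session("temp_responder", seed = 8)
  clean <- preprocess(ses$recording)
  defaults <- detector_params()
  g <- tailor_grid(a_edr = defaults$a_edr, dt_min = defaults$dt_min,
                   min_peak_prominence = defaults$min_peak_prominence,
                   weights = list(c(1, 1, 1)))
  fit <- fit_from_annotations(clean, NULL, ses$annotations, grid = g,
                              seed_candidates = FALSE)
  expect_equal(unclass(fit$params), unclass(defaults))
})

test_that("tailoring never scores below the defaults when defaults are searched", {
  for (s in c(4, 9)) {
    ses <- reference_session("temp_responder", seed = s)
    clean <- preprocess(ses$recording)
    sqi <- compute_sqi(clean)
    base_ev <- run_detector(clean, sqi, detector_params())
    base_prec <- evaluate_events(base_ev, ses$annotations)$precision
    fit <- fit_from_annotations(clean, sqi, ses$annotations)
    expect_gte(fit$precision, base_prec)
  }
})

test_that("all-true-positive feedback leaves parameters unchanged", {
  ses <- reference_session("eda_responder", seed = 31)
  clean <- preprocess(ses$recording)
  sqi <- compute_sqi(clean)
  params <- fit_from_annotations(clean, sqi, ses$annotations)$params
  ev <- run_detector(clean, sqi, params)
  fb <- tibble::tibble(time_s = ev$time_s, verdict = "TP")
  out <- iterate_feedback(params, clean, sqi, fb)
  expect_equal(unclass(out$params), unclass(params))
})

test_that("feedback raises a threshold past an isolated weak false positive", {
  # annotated events at 0.24 uS; one unannotated 0.08 uS bump fools the
  # default threshold
  cfg <- synth_config(
    duration_s = 300, seed = 77,
    events = tibble::tibble(time_s = c(50, 120, 240), modality = "eda",
                            magnitude = 0.24, duration_s = 10),
    distractors = tibble::tibble(time_s = 180, modality = "eda",
                                 magnitude = 0.08, duration_s = 10))
  ses <- generate_session(cfg)
  clean <- preprocess(ses$recording)
  sqi <- compute_sqi(clean)
  # temperature threshold pre-raised above the session drift so that the
  # electrodermal bump is the single false positive
  params <- detector_params(dt_min = 0.05)    # a_edr stays at 0.05
  ev <- run_detector(clean, sqi, params)
  ematch <- evaluate_events(ev, ses$annotations)
  expect_equal(ematch$fp, 1)                  # the bump is detected

  verdicts <- ifelse(vapply(ev$time_s, function(tt) {
    any(abs(ses$annotations$time_s - tt) <= 10)
  }, logical(1)), "TP", "FP")
  fb <- tibble::tibble(time_s = ev$time_s, verdict = verdicts)
  out <- iterate_feedback(params, clean, sqi, fb,
                          grid = tailor_grid(a_edr = c(0.05, 0.1, 0.2)))
  expect_gt(out$params$a_edr, 0.08)
  expect_lte(out$params$a_edr, 0.2)
  ev2 <- run_detector(clean, sqi, out$params)
  expect_equal(evaluate_events(ev2, ses$annotations)$fp, 0)
  expect_equal(evaluate_events(ev2, ses$annotations)$tp, 3)
})

test_that("feedback lowers a threshold to recover a reported missed moment", {
  # a 0.15 degC warming step missed under dt_min = 0.2
  t2 <- seq(0, 200, by = 0.5)
  temp <- 33 + 0.15 * pmin(pmax((t2 - 95) / 5, 0), 1)
  clean <- make_clean(t2, temp = temp)
  params <- detector_params(dt_min = 0.2)
  expect_equal(nrow(run_detector(clean, NULL, params)), 0)

  fb <- tibble::tibble(time_s = 40, verdict = "TP")  # placeholder verdict
  out <- iterate_feedback(params, clean, NULL, fb, missed = 100,
                          grid = tailor_grid(dt_min = c(0.1, 0.15, 0.2, 0.3)))
  expect_lte(out$params$dt_min, 0.15)
  ev2 <- run_detector(clean, NULL, out$params)
  expect_true(any(abs(ev2$time_s - 100) <= 10))
})

test_that("empty or malformed feedback is rejected", {
  ses <- reference_session("eda_responder", seed = 1, duration_s = 120)
  clean <- preprocess(ses$recording)
  expect_error(iterate_feedback(detector_params(), clean, NULL,
                                tibble::tibble(time_s = numeric(0),
                                               verdict = character(0))),
               class = "physioevents_validation_error")
  expect_error(iterate_feedback(detector_params(), clean, NULL,
                                tibble::tibble(time_s = 1, verdict = "eh")),
               class = "physioevents_validation_error")
})
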