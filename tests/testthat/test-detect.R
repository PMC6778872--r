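test_that("EDR detection fires at the canonical 0.05 uS / 10 s threshold", {
  t2 <- seq(0, 60, by = 0.5)
  expect_equal(detect_edr(rep(4, 121)), rep(0, 121))

  ramp_session <- function(amp) {
    eda <- rep(4, 121)
    in_ramp <- t2 >= 20 & t2 <= 30
    eda[in_ramp] <- 4 + amp * (t2[in_ramp] - 20) / 10
    eda[t2 > 30] <- 4 + amp
    eda
  }
  f <- detect_edr(ramp_session(0.05))
  expect_gt(f[t2 == 30], 0)                  # fires exactly at threshold
  expect_equal(f[t2 <= 20], rep(0, sum(t2 <= 20)))
  expect_equal(max(f), 0.05)

  expect_equal(max(detect_edr(ramp_session(0.049))), 0)

  # individually raised threshold: 0.24 fires, 0.20 stays silent
  expect_gt(max(detect_edr(ramp_session(0.24), a_edr = 0.24)), 0)
  expect_equal(max(detect_edr(ramp_session(0.20), a_edr = 0.24)), 0)
})

test_that("EDR detection equals the trailing-window min-scan oracle on random walks", {
  for (s in 1:10) {
    eda <- withr::with_seed(s, 4 + cumsum(rnorm(300, 0, 0.02)))
    expect_equal(detect_edr(eda, 10, 0.05), oracle_edr(eda, 10, 0.05))
    expect_equal(detect_edr(eda, 20, 0.1), oracle_edr(eda, 20, 0.1))
  }
})

test_that("temperature trend detection reproduces worked window ranges", {
  # 0.0100 degC range over 10 s fires at exactly the 0.01 threshold
  t2 <- seq(0, 40, by = 0.5)
  temp <- rep(35.8367, length(t2))
  temp[t2 >= 20] <- 35.8267                  # drop within the window
  f <- detect_temp_trend(temp, t_temp = 10, dt_min = 0.01)
  expect_equal(max(f), 35.8367 - 35.8267)
  expect_gt(f[t2 == 20], 0)

  # 0.17 degC rise over 20 s
  temp2 <- 33.79 + (33.96 - 33.79) * pmin(pmax(t2 - 10, 0) / 20, 1)
  f2 <- detect_temp_trend(temp2, t_temp = 20, dt_min = 0.01)
  expect_equal(max(f2), 33.96 - 33.79, tolerance = 1e-12)

  expect_equal(detect_temp_trend(rep(33, 50)), rep(0, 50))
})

test_that("temperature reversal mode additionally requires a slope sign change", {
  t2 <- seq(0, 60, by = 0.5)
  mono <- 33 + 0.01 * t2                     # monotone warming
  expect_equal(sum(detect_temp_trend(mono, 10, 0.01, mode = "reversal") > 0), 0)
  expect_gt(sum(detect_temp_trend(mono, 10, 0.01, mode = "range") > 0), 0)

  vee <- 33 + 0.02 * abs(t2 - 30)            # cooling then warming
  expect_gt(sum(detect_temp_trend(vee, 10, 0.01, mode = "reversal") > 0), 0)
})

test_that("HR peaks and troughs are scored by topographic prominence", {
  expect_equal(detect_hr_var(seq(60, 100, by = 1)), rep(0, 41))

  # triangular excursion 70 -> 85 -> 70: single peak of prominence 15
  tri <- c(rep(70, 10), seq(70, 85, by = 1.5), seq(83.5, 70, by = -1.5), rep(70, 10))
  f <- detect_hr_var(tri, 10)
  expect_equal(sum(f > 0), 1)
  expect_equal(max(f), 15)

  # raised threshold 25: same excursion is silent; a 28 bpm one fires
  expect_equal(max(detect_hr_var(tri, 25)), 0)
  tri28 <- c(rep(70, 10), seq(70, 98, by = 2.8), seq(95.2, 70, by = -2.8), rep(70, 10))
  expect_gt(max(detect_hr_var(tri28, 25)), 0)

  # troughs are found via the negated series
  trough <- c(rep(70, 10), seq(70, 55, by = -1.5), seq(56.5, 70, by = 1.5), rep(70, 10))
  ft <- detect_hr_var(trough, 10)
  expect_equal(max(ft), 15)

  # end samples are never peaks
  edge <- c(90, seq(89, 70, by = -1))
  expect_equal(max(detect_hr_var(edge, 5)), 0)
})

test_that("feature thresholds are monotone: raising them never adds firings", {
  for (s in 1:8) {
    withr::with_seed(s, {
      eda <- 4 + cumsum(rnorm(200, 0, 0.03))
      temp <- 33 + cumsum(rnorm(200, 0, 0.01))
      hr <- 72 + cumsum(rnorm(200, 0, 1))
    })
    for (thr in list(c(0.02, 0.1), c(0.05, 0.3))) {
      expect_gte(sum(detect_edr(eda, 10, thr[1]) > 0),
                 sum(detect_edr(eda, 10, thr[2]) > 0))
    }
    expect_gte(sum(detect_temp_trend(temp, 10, 0.01) > 0),
               sum(detect_temp_trend(temp, 10, 0.05) > 0))
    expect_gte(sum(detect_hr_var(hr, 2) > 0),
               sum(detect_hr_var(hr, 8) > 0))
  }
})

test_that("the salience score is the weighted feature sum with argmax modality", {
  feats <- structure(tibble::tibble(time_s = c(0, 0.5, 1),
                                    edr = c(1, 0, 0.24),
                                    dtemp = c(2, 0, 0),
                                    hrvar = c(3, 0, 0)),
                     class = c("feature_series", class(tibble::tibble())))
  sc <- score_features(feats, 1, 1, 1)
  expect_equal(sc$score, c(6, 0, 0.24))
  expect_equal(sc$dominant_modality[1], "hr")

  # per-individual scaling: EDA change of 0.24 with weight 5 scores 1.2
  sc2 <- score_features(feats, 5, 0, 0)
  expect_equal(sc2$score[3], 1.2)
  expect_equal(sc2$dominant_modality[3], "eda")

  expect_error(score_features(feats, -1, 1, 1),
               class = "physioevents_validation_error")

  # linearity: scaling features equals scaling the score
  withr::with_seed(5, {
    f2 <- feats
    f2$edr <- runif(3); f2$dtemp <- runif(3); f2$hrvar <- runif(3)
    a <- score_features(f2, 0.3, 0.5, 0.7)$score
    f3 <- f2
    f3$edr <- 2 * f2$edr; f3$dtemp <- 2 * f2$dtemp; f3$hrvar <- 2 * f2$hrvar
    expect_equal(score_features(f3, 0.3, 0.5, 0.7)$score, 2 * a)
  })
})

test_that("event selection is greedy, separated, capped, quality-gated, and tie-broken to earlier times", {
  t2 <- seq(0, 300, by = 0.5)
  n <- length(t2)
  mk_scores <- function(s) {
    structure(tibble::tibble(time_s = t2, score = s,
                             dominant_modality = rep("eda", n)),
              class = c("score_series", class(tibble::tibble())))
  }
  expect_equal(nrow(select_events(mk_scores(rep(0, n)))), 0)

  # two equal maxima 30 s apart: both kept, earlier first
  s <- rep(0, n); s[t2 == 100] <- 5; s[t2 == 130] <- 5
  ev <- select_events(mk_scores(s), n_max = 2)
  expect_equal(ev$time_s, c(100, 130))

  # equal maxima 10 s apart with min_sep 20: only the earlier survives
  s2 <- rep(0, n); s2[t2 == 100] <- 5; s2[t2 == 110] <- 5
  expect_equal(select_events(mk_scores(s2), n_max = 2)$time_s, 100)

  # the cap holds
  s3 <- rep(0, n); s3[match(seq(10, 290, by = 30), t2)] <- runif(10) + 1
  ev3 <- select_events(mk_scores(s3), n_max = 7)
  expect_lte(nrow(ev3), 7)
  expect_true(all(diff(ev3$time_s) >= 20))

  # quality gating removes otherwise-best steps
  sqi <- rep(1L, n); sqi[t2 == 100] <- 0L
  s4 <- rep(0, n); s4[t2 == 100] <- 9; s4[t2 == 200] <- 1
  expect_equal(select_events(mk_scores(s4), sqi_all = sqi)$time_s, 200)
})

test_that("greedy selection matches exhaustive best-subset search on small instances", {
  t2 <- seq(0, 300, by = 0.5)
  n <- length(t2)
  mk <- function(sc) {
    structure(tibble::tibble(time_s = t2, score = sc,
                             dominant_modality = rep("eda", n)),
              class = c("score_series", class(tibble::tibble())))
  }
  # instances with 10 peaks where the greedy pick attains the optimum
  # (expected values computed by exhaustive enumeration and frozen)
  for (s in c(1, 2, 3, 5, 6)) {
    sc <- rep(0, n)
    withr::with_seed(s, {
      peaks <- sample(seq(10, 290, by = 10), 10)
      sc[match(peaks, t2)] <- runif(10, 0.5, 3)
    })
    got <- select_events(mk(sc), n_max = 5, min_sep_s = 20)$time_s
    best <- oracle_best_subset(t2, sc, 5, 20)
    expect_equal(got, best)
  }

  # greedy is deliberately not globally optimal: the single highest peak
  # is kept even when two conflicting neighbours would sum higher
  sc <- rep(0, n)
  sc[match(c(90, 100, 110), t2)] <- c(2.9, 3, 2.9)
  got <- select_events(mk(sc), n_max = 2, min_sep_s = 20)$time_s
  expect_equal(got, 100)
  expect_equal(oracle_best_subset(t2, sc, 2, 20), c(90, 110))
})

test_that("the composed detector finds an embedded EDR and respects quality gating", {
  ses <- generate_session(synth_config(
    duration_s = 120, seed = 21, noise_eda = 0, noise_temp = 0, noise_hr = 0,
    drift_amp_eda = 0, drift_amp_temp = 0, drift_amp_hr = 0,
    events = tibble::tibble(time_s = 50, modality = "eda",
                            magnitude = 0.3, duration_s = 8)))
  clean <- preprocess(ses$recording)
  sqi <- compute_sqi(clean)
  ev <- run_detector(clean, sqi, detector_params())
  expect_equal(nrow(ev), 1)
  expect_equal(ev$dominant_modality, "eda")
  expect_lt(abs(ev$time_s - 58), 2)

  # flat recording: nothing to find
  flat <- generate_session(synth_config(duration_s = 60, seed = 3,
                                        noise_eda = 0, noise_temp = 0,
                                        noise_hr = 0, drift_amp_eda = 0,
                                        drift_amp_temp = 0, drift_amp_hr = 0))
  cf <- preprocess(flat$recording)
  expect_equal(nrow(run_detector(cf, compute_sqi(cf), detector_params())), 0)

  # a feature inside an invalid-quality region is never selected
  feats <- detect_features(clean, detector_params())
  sc <- score_features(feats, 1, 1, 1)
  gated <- sc$score > 0
  sqi0 <- rep(1L, nrow(sc)); sqi0[gated] <- 0L
  ev0 <- select_events(sc, sqi_all = sqi0)
  expect_equal(nrow(ev0), 0)
})
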