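test_that("identical seeds reproduce a session exactly", {
  cfg <- generator_config(n_dyads = 1L, n_grades = 3L,
                          grade_duration_s = 40)
  s1 <- generate_session(cfg, seed = 99)
  s2 <- generate_session(cfg, seed = 99)
  expect_identical(s1$events, s2$events)
  expect_identical(s1$front$x, s2$front$x)
  expect_identical(s1$acoustics, s2$acoustics)
  expect_identical(s1$envelope, s2$envelope)
  s3 <- generate_session(cfg, seed = 100)
  expect_false(identical(s1$events, s3$events))
})

test_that("zero-noise gestures yield exact feature recovery", {
  cfg <- generator_config(n_dyads = 1L, n_grades = 3L,
                          grade_duration_s = 60, keypoint_noise_px = 0,
                          torso_sway_px = 0, amplitude_log_sd = 0)
  ses <- generate_session(cfg, seed = 41)
  tr <- ses$truth$events
  for (i in seq_len(min(nrow(tr), 6))) {
    ev <- ses$events[i, ]
    prof <- velocity_profile(ses$front, ev)
    sm <- detect_submovements(prof)
    expect_equal(sm$count, tr$k[i])
    expect_equal(peak_velocity(prof), tr$peak_speed[i],
                 tolerance = 0.03)
    expect_lt(abs(hold_time(prof, sm) - tr$hold_s[i]),
              2 * max(tr$k[i] - 1, 1) / cfg$fps + 1e-6)
    expect_equal(gesture_depth(ses$side, ev), tr$depth_px[i],
                 tolerance = 0.03 * tr$depth_px[i])
  }
})

test_that("feature bias shrinks as keypoint noise shrinks", {
  errs <- vapply(c(2, 0.5, 0), function(nz) {
    cfg <- generator_config(n_dyads = 1L, n_grades = 3L,
                            grade_duration_s = 60,
                            keypoint_noise_px = nz, torso_sway_px = 0,
                            amplitude_log_sd = 0)
    ses <- generate_session(cfg, seed = 42)
    tr <- ses$truth$events
    mean(vapply(seq_len(nrow(tr)), function(i) {
      p <- velocity_profile(ses$front, ses$events[i, ])
      abs(peak_velocity(p) - tr$peak_speed[i]) / tr$peak_speed[i]
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
  expect_lt(errs[3], 0.05)
})

test_that("generated studies round-trip through the readers unchanged", {
  cfg <- generator_config(n_dyads = 1L, n_grades = 2L,
                          grade_duration_s = 20)
  dir <- withr::local_tempdir()
  st <- generate_study(cfg, dir, seed = 43)
  expect_length(st$participants, 2)
  pdir <- file.path(dir, st$participants[1])
  ses <- generate_session(cfg, "d01", st$participants[1],
                          "clear_to_blur", seed = 43 * 1000L + 11L)
  front <- read_keypoints(file.path(pdir, "front.json"), "front")
  expect_equal(front$fps, cfg$fps)
  expect_equal(front$x, ses$front$x, tolerance = 1e-4,
               ignore_attr = TRUE)
  ev <- read_annotations(file.path(pdir, "events.tsv"),
                         ses$schedule)
  expect_equal(ev$start_s, ses$events$start_s, tolerance = 1e-9)
  expect_equal(ev$blur_grade, ses$events$blur_grade)
  # truth CSV has one row per generated gesture across participants
  truth <- read.csv(file.path(dir, "truth.csv"))
  n_events <- sum(vapply(st$participants, function(p)
    nrow(read.delim(file.path(dir, p, "events.tsv"))), numeric(1)))
  expect_equal(nrow(truth), n_events)
  expect_equal(nrow(st$truth), n_events)
})

test_that("events land inside speech and carry grade-dependent rates", {
  cfg <- generator_config(n_dyads = 1L)
  ses <- generate_session(cfg, seed = 44, streams = c("events",
                                                      "acoustics"))
  ev <- ses$events
  expect_gt(nrow(ev), 50)
  # every gesture overlaps speech (co-speech by construction)
  iv <- ses$speech_intervals
  inside <- vapply(seq_len(nrow(ev)), function(i)
    any(ev$start_s[i] >= iv[, 1] & ev$start_s[i] <= iv[, 2]),
    logical(1))
  expect_true(all(inside))
  # no same-participant overlap
  expect_true(all(ev$start_s[-1] >= ev$end_s[-nrow(ev)]))
  # infeasible rate errors out
  expect_error(
    generate_session(generator_config(gesture_rate_per_min = 200),
                     seed = 1, streams = "events"), "infeasible")
})

test_that("the coupling lag is recoverable from session streams", {
  cfg <- generator_config(n_dyads = 1L, n_grades = 2L,
                          grade_duration_s = 60, coupling_lag_ms = 50)
  ses <- generate_session(cfg, seed = 45)
  ev <- ses$events[1, ]
  win <- c(max(ev$start_s - 0.5, 0),
           min(ev$end_s + 0.5, max(ses$hand_speed$time)))
  pair <- merge_streams(
    data.frame(time = ses$envelope$time, value = ses$envelope$value),
    ses$hand_speed, rate = 32, window = win)
  msk <- significance_mask(pair, n_surrogates = 100, seed = 6)
  s <- summarize_alignment(msk)
  expect_false(is.null(s))
  expect_equal(s$phase_asynchrony_ms, ses$truth$expected_phase_ms,
               tolerance = 25)
})
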