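test_that("study design validates its fields", {
  d <- study_design(n_participants = 4)
  expect_s3_class(d, "icuvr_design")
  expect_length(d$target_epochs, 3)
  expect_true(all(d$target_epochs[[1]] >= 0 & d$target_epochs[[1]] <= 300))
  expect_error(study_design(n_participants = 0), "n_participants")
  expect_error(study_design(gaze_rate = -1), "gaze_rate")
  expect_error(study_design(n_videos = 1,
                            target_epochs = list(matrix(c(100, 400), 1))),
               "video_duration")
  expect_error(study_design(n_videos = 1,
                            target_epochs = list(rbind(c(50, 40)))),
               "end_s > start_s")
})

test_that("gaze generator is seed-deterministic and honours blink structure", {
  d <- study_design(n_participants = 1, n_videos = 1, video_duration = 30,
                    seed = 8)
  g1 <- simulate_gaze(d, seed = 8)
  g2 <- simulate_gaze(d, seed = 8)
  expect_identical(g1$samples, g2$samples)
  expect_identical(g1$events, g2$events)

  # no blinks -> all samples valid
  tq <- gaze_truth_params(blink_rate_per_min = 0,
                          long_closure_rate_per_min = 0)
  g0 <- simulate_gaze(d, tq, seed = 8)
  expect_true(all(g0$samples$valid))

  # blink intervals are disjoint and samples inside them invalid
  expect_true(nrow(g1$blinks) == 0 ||
                all(g1$blinks$end >= g1$blinks$start))
  if (nrow(g1$blinks) > 1)
    expect_true(all(g1$blinks$start[-1] > g1$blinks$end[-nrow(g1$blinks)]))
})

test_that("gaze ground truth tiles the video and orders target contrasts", {
  d <- study_design(n_participants = 1, n_videos = 1, video_duration = 60,
                    seed = 3)
  g <- simulate_gaze(d, seed = 3)
  ev <- g$events
  # events tile [0, duration]: consecutive, no gaps
  expect_equal(ev$start[1], 0)
  expect_equal(ev$start[-1], ev$end[-nrow(ev)], tolerance = 1e-9)
  expect_equal(max(ev$end), 60, tolerance = 1e-9)
  # target flags consistent with the design epochs
  ep <- d$target_epochs[[1]]
  inside <- rep(FALSE, nrow(g$samples))
  for (k in seq_len(nrow(ep)))
    inside <- inside | (g$samples$t >= ep[k, 1] & g$samples$t <= ep[k, 2])
  expect_equal(g$samples$target, as.integer(inside))
  # mean true fixation duration: target-present > target-absent
  fx <- ev[ev$type == "fixation", ]
  expect_gt(mean(fx$duration_ms[fx$target == 1]),
            mean(fx$duration_ms[fx$target == 0]))
})

test_that("gaze truth parameters reject ill-ordered regimes", {
  expect_error(gaze_truth_params(fix_dur_ms = c(absent = 300, present = 200)),
               "fix_dur_ms")
  expect_error(gaze_truth_params(wander_dur_s = c(absent = 0.2,
                                                  present = 0.9)),
               "wander_dur_s")
  expect_error(gaze_truth_params(drift_speed_deg_s = 0), "drift_speed")
})

test_that("eye-frame generator matches its stated geometry", {
  # noiseless open frame: the darkest pixel set is exactly the disc
  fr <- simulate_eye_frames(1, c(40, 30), 10, image_size_px = c(80, 60),
                            noise_sd = 0)
  img <- fr$frames[[1]]
  xs <- matrix(rep(seq_len(80), each = 60), nrow = 60)
  ys <- matrix(rep(seq_len(60), times = 80), nrow = 60)
  disc <- (xs - 40)^2 + (ys - 30)^2 <= 100
  expect_true(all(img[disc] < img[!disc][1]))
  expect_identical(unname(img == min(img)), unname(disc))

  # all frames closed -> no disc anywhere
  frc <- simulate_eye_frames(3, c(40, 30), 10, closure_frames = 1:3,
                             image_size_px = c(80, 60), noise_sd = 0)
  expect_true(all(vapply(frc$frames, function(m) length(unique(c(m))) == 1,
                         TRUE)))

  # pupil out of bounds rejected; determinism
  expect_error(simulate_eye_frames(1, c(5, 30), 10,
                                   image_size_px = c(80, 60)),
               "inside the frame")
  a <- simulate_eye_frames(2, c(40, 30), 10, image_size_px = c(80, 60),
                           noise_sd = 4, seed = 5)
  b <- simulate_eye_frames(2, c(40, 30), 10, image_size_px = c(80, 60),
                           noise_sd = 4, seed = 5)
  expect_identical(a$frames, b$frames)
})

test_that("vitals generator reproduces the deterministic fixed-effect line", {
  d <- study_design(n_participants = 3, seed = 2)
  tr0 <- vital_truth_params(
    beta_time = c(hf = 0, map = 0, rf = 0, spo2 = 0),
    beta_age_time = c(hf = 0, map = 0, rf = 0, spo2 = 0),
    intercept_sd = c(hf = 0, map = 0, rf = 0, spo2 = 0),
    slope_sd = c(hf = 0, map = 0, rf = 0, spo2 = 0),
    residual_sd = c(hf = 0, map = 0, rf = 0, spo2 = 0))
  v <- simulate_vitals(d, tr0, ages = c(30, 50, 70), seed = 2)
  expect_true(all(v$hf == 68) && all(v$map == 87) && all(v$rf == 21) &&
                all(v$spo2 == 97))

  # non-zero slope, still deterministic: exact linear trend
  tr1 <- tr0; tr1$beta_time["map"] <- -0.5
  v1 <- simulate_vitals(d, tr1, ages = c(30, 50, 70), seed = 2)
  expect_equal(v1$map, 87 - 0.5 * v1$time_index, tolerance = 1e-12)

  # determinism and SpO2 clipping
  v2 <- simulate_vitals(d, ages = c(30, 50, 70), seed = 9)
  v3 <- simulate_vitals(d, ages = c(30, 50, 70), seed = 9)
  expect_identical(v2, v3)
  expect_true(all(v2$spo2 <= 100 & v2$spo2 >= 0))
  expect_error(simulate_vitals(d, ages = c(30, 50)), "one entry per")
})

test_that("vital truth parameters validate SDs and correlation", {
  expect_error(vital_truth_params(
    intercept_slope_corr = c(hf = -2, map = 0, rf = 0, spo2 = 0)),
    "\\[-1, 1\\]")
  expect_error(vital_truth_params(
    residual_sd = c(hf = -1, map = 1, rf = 1, spo2 = 1)),
    "non-negative")
})

test_that("questionnaire generator hits requested moments and validates", {
  q0 <- simulate_questionnaire(scale_means = c(presence = 3.2),
                               scale_sds = c(presence = 0), n = 10)
  expect_true(all(q0$presence == 3.2))
  q1 <- simulate_questionnaire(n = 200, seed = 4)
  q2 <- simulate_questionnaire(n = 200, seed = 4)
  expect_identical(q1, q2)
  # empirical mean within 3 SE of request (clipping keeps these scales mild)
  expect_lt(abs(mean(q1$presence) - 3.11), 3 * 1.1 / sqrt(200) + 0.1)
  expect_true(all(as.matrix(q1[-1]) >= 1 & as.matrix(q1[-1]) <= 5))
  expect_error(simulate_questionnaire(scale_means = c(a = 0.5),
                                      scale_sds = c(a = 1)),
               "rating scale")
})
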