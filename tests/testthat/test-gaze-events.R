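test_that("resampling leaves a uniform 60 Hz trace unchanged and interpolates ramps exactly", {
  tr <- stable_trace(61)
  tr$x <- rnorm(61)
  out <- resample_gaze(tr)
  expect_equal(out$t, tr$t)
  expect_equal(out$x, tr$x)

  # 30 Hz linear ramp x(t) = t -> 60 Hz samples lie exactly on the ramp
  tr30 <- data.frame(t = (0:30) / 30, x = (0:30) / 30, y = 0, valid = TRUE)
  out30 <- resample_gaze(tr30)
  expect_equal(out30$x, out30$t, tolerance = 1e-12)
  expect_equal(length(out30$t), 61)

  # 120 Hz input halves (+-1)
  tr120 <- data.frame(t = (0:120) / 120, x = 0, y = 0, valid = TRUE)
  out120 <- resample_gaze(tr120)
  expect_true(abs(nrow(out120) - 61) <= 1)

  expect_error(resample_gaze(data.frame(t = c(0, 0), x = 0, y = 0,
                                        valid = TRUE)),
               "strictly increasing")
})

test_that("resampled validity requires both bracketing samples valid", {
  tr <- data.frame(t = (0:10) / 60, x = 0, y = 0, valid = TRUE)
  tr$valid[5] <- FALSE
  out <- resample_gaze(tr)
  expect_false(out$valid[5])    # exact hit on the invalid sample
  expect_true(all(out$valid[-5]))
})

test_that("closure-gap removal is strict at the 20-frame limit", {
  mk <- function(run) {
    tr <- stable_trace(100)
    tr$valid[40:(40 + run - 1)] <- FALSE
    tr
  }
  out21 <- remove_closure_gaps(mk(21))
  expect_equal(nrow(out21), 100 - 21)           # run of 21 deleted
  out20 <- remove_closure_gaps(mk(20))
  expect_equal(nrow(out20), 100)                # run of 20 retained
  expect_true(all(out20$valid))                 # interpolated through
  tr <- stable_trace(50)
  expect_identical(remove_closure_gaps(tr), tr) # all-valid identity
})

test_that("retained closure gaps are linearly interpolated", {
  tr <- stable_trace(60)
  tr$x <- seq(0, 5.9, by = 0.1)
  tr$valid[20:25] <- FALSE
  tr$x[20:25] <- 99  # garbage during closure
  out <- remove_closure_gaps(tr)
  expect_equal(out$x[20:25], seq(0, 5.9, by = 0.1)[20:25], tolerance = 1e-9)
})

test_that("I-DT detects simple constructed events exactly", {
  # 200 ms of constant gaze -> one fixation of 200 ms, no saccades
  ev <- detect_fixations(stable_trace(13))
  expect_equal(nrow(ev$fixations), 1)
  expect_equal(ev$fixations$duration_ms, 200, tolerance = 1e-6)
  expect_equal(nrow(ev$saccades), 0)

  # two 150 ms clusters 10 degrees apart -> two fixations, one 10.0 deg saccade
  tr <- rbind(stable_trace(10, x0 = 0),
              stable_trace(10, x0 = 10, t0 = 10 / 60))
  ev2 <- detect_fixations(tr)
  expect_equal(nrow(ev2$fixations), 2)
  expect_equal(nrow(ev2$saccades), 1)
  expect_equal(ev2$saccades$amplitude, 10, tolerance = 1e-9)

  # fast ramp exceeding 2 deg dispersion in every 100 ms span -> no fixation
  ramp <- data.frame(t = (0:120) / 60, x = (0:120) * 0.5, y = 0)
  ev3 <- detect_fixations(ramp)
  expect_equal(nrow(ev3$fixations), 0)
})

test_that("the 100 ms minimum duration is inclusive", {
  # 7 samples at 60 Hz span exactly 100 ms -> one fixation
  ev_ok <- detect_fixations(stable_trace(7))
  expect_equal(nrow(ev_ok$fixations), 1)
  # 6 samples span 83 ms -> none
  ev_no <- detect_fixations(stable_trace(6))
  expect_equal(nrow(ev_no$fixations), 0)
  # 99 ms cluster at 1000 Hz -> none; 100 ms -> one
  t99 <- data.frame(t = seq(0, 0.099, by = 0.001), x = 0, y = 0)
  expect_equal(nrow(detect_fixations(t99)$fixations), 0)
  t100 <- data.frame(t = seq(0, 0.100, by = 0.001), x = 0, y = 0)
  expect_equal(nrow(detect_fixations(t100)$fixations), 1)
})

test_that("I-DT matches the brute-force oracle on random traces", {
  for (seed in 1:25) {
    tr <- random_trace(sample(200:2000, 1), seed = seed)
    got <- detect_fixations(tr)
    exp <- oracle_idt(tr$t, tr$x, tr$y)
    expect_equal(nrow(got$fixations), nrow(exp), label = paste("seed", seed))
    if (nrow(exp) > 0) {
      expect_true(all(abs(got$fixations$start - tr$t[exp[, "start"]]) <=
                        1 / 60 + 1e-9))
      expect_true(all(abs(got$fixations$end - tr$t[exp[, "end"]]) <=
                        1 / 60 + 1e-9))
    }
  }
})

test_that("raising the dispersion threshold never decreases total fixation time", {
  for (seed in 26:32) {
    tr <- random_trace(800, seed = seed)
    tot <- vapply(c(0.5, 1, 2, 4, 8), function(d)
      sum(detect_fixations(tr, max_dispersion_deg = d)$fixations$duration_ms),
      0)
    expect_true(all(diff(tot) >= -1e-9), label = paste("seed", seed))
  }
})

test_that("fixation and non-fixation time partition the trace", {
  tr <- random_trace(1500, seed = 99)
  ev <- detect_fixations(tr)
  span <- tr$t[nrow(tr)] - tr$t[1]
  fix_time <- sum(ev$fixations$end - ev$fixations$start)
  # fixations are disjoint and inside the trace
  expect_true(all(diff(as.vector(t(ev$fixations[c("start", "end")]))) >= 0))
  expect_lte(fix_time, span)
  expect_equal(fix_time + (span - fix_time), span)
})

test_that("windowed features match a stationary construction", {
  # one 200 ms fixation per second, exactly
  n_sec <- 120
  pieces <- lapply(seq_len(n_sec), function(k) {
    fix <- stable_trace(13, x0 = 30 * (k %% 2), t0 = (k - 1))
    move <- data.frame(t = (k - 1) + (13:59) / 60,
                       x = seq(30 * (k %% 2), 30 * ((k + 1) %% 2),
                               length.out = 47),
                       y = 0, valid = TRUE)
    rbind(fix, move)
  })
  tr <- do.call(rbind, pieces)
  ev <- detect_fixations(tr)
  ft <- sliding_window_features(ev$fixations, ev$saccades, tr,
                                window_s = 60, step_s = 1)
  interior <- ft$t > 31 & ft$t < n_sec - 31
  expect_equal(mean(ft$n_fix_per_s[interior]), 1.0, tolerance = 0.05)
  expect_equal(mean(ft$fix_dur_ms_per_s[interior]), 200, tolerance = 10)
})

test_that("windows without saccades emit missing ratio and amplitude", {
  tr <- stable_trace(1200)  # 20 s of constant gaze, single fixation
  ev <- detect_fixations(tr)
  ft <- sliding_window_features(ev$fixations, ev$saccades, tr,
                                window_s = 10, step_s = 1)
  expect_true(all(is.na(ft$fix_sacc_ratio)))
  expect_true(all(is.na(ft$sacc_amp_deg)))
  expect_error(sliding_window_features(ev$fixations, ev$saccades, tr,
                                       window_s = -1), "positive")
})

test_that("target epochs with longer fixations raise the windowed ratio", {
  d <- study_design(n_participants = 1, n_videos = 1, video_duration = 120,
                    seed = 21)
  g <- simulate_gaze(d, seed = 21)
  tr <- remove_closure_gaps(resample_gaze(g$samples))
  ev <- detect_fixations(tr)
  ft <- sliding_window_features(ev$fixations, ev$saccades, tr,
                                window_s = 20, step_s = 1)
  expect_gt(mean(ft$fix_sacc_ratio[ft$target == 1], na.rm = TRUE),
            mean(ft$fix_sacc_ratio[ft$target == 0], na.rm = TRUE))
})
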