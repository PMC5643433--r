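#' Ground-truth parameters for synthetic gaze traces
#'
#' The generator alternates fixations with non-fixation exploration
#' ("wander") intervals. During target-present epochs fixations are longer
#' and exploration shorter, so fixation counts and durations rise and the
#' net gaze shift between consecutive fixations (the detected saccade
#' amplitude) shrinks — the direction of the target effects the feature
#' models are meant to pick up. Defaults are tuned so that, in the
#' target-absent state, pooled windowed features land near realistic values
#' for free viewing of dynamic natural scenes in a wide field of view
#' (about 0.8 fixations/s, 170 ms/s fixation time, 14 degree shifts).
#'
#' @param fix_dur_ms named vector `c(absent=, present=)` of mean fixation
#'   durations in ms; `present` must exceed `absent`.
#' @param fix_dur_shape gamma shape for fixation durations; `Inf` makes all
#'   durations exactly equal to the mean.
#' @param wander_dur_s named vector `c(absent=, present=)` of mean
#'   exploration durations in seconds; `present` must be below `absent` so
#'   target-present gaze shifts are smaller. Setting both to 0 replaces
#'   exploration by single-sample jumps to a fresh landing point.
#' @param wander_dur_shape gamma shape for exploration durations.
#' @param drift_speed_deg_s gaze speed during exploration (deg/s); must be
#'   fast enough to exceed the I-DT dispersion criterion over 100 ms.
#' @param wander_segment_s mean duration of the straight legs of the
#'   exploration path; at leg boundaries the heading turns by a random
#'   30-120 degrees (either side), so the path changes direction without
#'   ever dwelling inside the dispersion criterion.
#' @param landing_sd_deg named vector `c(absent=, present=)`: SD (deg) of the
#'   landing point around screen centre, used only in jump mode.
#' @param jitter_sd_deg isotropic SD of within-fixation gaze jitter, deg.
#' @param field_half_deg half-extent of the gaze field in degrees.
#' @param blink_rate_per_min rate of short blinks (invalid gaps well below
#'   the closure-removal limit).
#' @param long_closure_rate_per_min rate of long eye closures (gaps beyond
#'   the 20-frame limit, removed downstream).
#'
#' @return A validated list of class `icuvr_gaze_truth`.
#' @export
gaze_truth_params <- function(fix_dur_ms = c(absent = 210, present = 290),
                              fix_dur_shape = 6,
                              wander_dur_s = c(absent = 1.0, present = 0.3),
                              wander_dur_shape = 3,
                              drift_speed_deg_s = 30,
                              wander_segment_s = 0.4,
                              landing_sd_deg = c(absent = 8, present = 1.5),
                              jitter_sd_deg = 0.15,
                              field_half_deg = 40,
                              blink_rate_per_min = 4,
                              long_closure_rate_per_min = 0.5) {
  need2 <- function(v, name) {
    if (!all(c("absent", "present") %in% names(v)))
      stop(sprintf("'%s' needs named entries 'absent' and 'present'", name),
           call. = FALSE)
    if (any(v < 0)) stop(sprintf("'%s' must be non-negative", name),
                         call. = FALSE)
  }
  need2(fix_dur_ms, "fix_dur_ms"); need2(wander_dur_s, "wander_dur_s")
  need2(landing_sd_deg, "landing_sd_deg")
  if (any(fix_dur_ms <= 0))
    stop("'fix_dur_ms' must be positive", call. = FALSE)
  if (fix_dur_ms["present"] <= fix_dur_ms["absent"])
    stop("'fix_dur_ms': target-present mean must exceed target-absent mean",
         call. = FALSE)
  jump_mode <- all(wander_dur_s == 0)
  if (!jump_mode && wander_dur_s["present"] > wander_dur_s["absent"])
    stop("'wander_dur_s': target-present mean must not exceed target-absent mean",
         call. = FALSE)
  if (jump_mode && landing_sd_deg["present"] >= landing_sd_deg["absent"])
    stop("'landing_sd_deg': target-present SD must be below target-absent SD",
         call. = FALSE)
  if (drift_speed_deg_s <= 0)
    stop("'drift_speed_deg_s' must be positive", call. = FALSE)
  if (jitter_sd_deg < 0)
    stop("'jitter_sd_deg' must be non-negative", call. = FALSE)
  structure(list(fix_dur_ms = fix_dur_ms, fix_dur_shape = fix_dur_shape,
                 wander_dur_s = wander_dur_s,
                 wander_dur_shape = wander_dur_shape,
                 drift_speed_deg_s = drift_speed_deg_s,
                 wander_segment_s = wander_segment_s,
                 landing_sd_deg = landing_sd_deg,
                 jitter_sd_deg = jitter_sd_deg,
                 field_half_deg = field_half_deg,
                 blink_rate_per_min = blink_rate_per_min,
                 long_closure_rate_per_min = long_closure_rate_per_min),
            class = "icuvr_gaze_truth")
}

rgamma_mean <- function(n, mean, shape) {
  if (is.infinite(shape)) rep(mean, n)
  else rgamma(n, shape = shape, scale = mean / shape)
}

# reflect a coordinate into [-b, b]
reflect_into <- function(x, b) {
  x <- (x + b) %% (4 * b)
  x <- ifelse(x > 2 * b, 4 * b - x, x)
  x - b
}

#' Simulate one 60 Hz gaze trace with ground truth
#'
#' Generates a single participant x video gaze trace under a study design:
#' alternating fixations (centroid plus isotropic jitter) and exploration
#' intervals (a constant-speed heading random walk, or single-sample jumps
#' in jump mode), with target-present epochs switching the event-duration
#' regimes, and blink/closure intervals flagged invalid.
#'
#' @param design an [study_design()] object.
#' @param truth a [gaze_truth_params()] object.
#' @param participant,video identifiers written into the output.
#' @param seed integer seed; identical seeds give identical traces.
#'
#' @return A list with `samples` (data.frame `participant_id, video, t, x,
#'   y, valid, target`), `events` (ground-truth fixations and exploration
#'   intervals with centroids, durations and shift amplitudes) and `blinks`
#'   (disjoint closure intervals in seconds).
#' @examples
#' d <- study_design(n_participants = 1, n_videos = 1, video_duration = 20)
#' g <- simulate_gaze(d, seed = 7)
#' head(g$samples)
#' @export
simulate_gaze <- function(design, truth = gaze_truth_params(),
                          participant = 1L, video = 1L,
                          seed = design$seed) {
  stopifnot(inherits(design, "icuvr_design"))
  stopifnot(inherits(truth, "icuvr_gaze_truth"))
  set.seed(as.integer(seed))
  rate <- design$gaze_rate
  dur <- design$video_duration
  dt <- 1 / rate
  ts <- seq(0, dur, by = dt)
  n <- length(ts)
  flags <- target_flag_at(design, video, ts)
  jump_mode <- all(truth$wander_dur_s == 0)
  b <- truth$field_half_deg

  x <- numeric(n); y <- numeric(n)
  ev_type <- character(0); ev_start <- ev_end <- ev_cx <- ev_cy <-
    ev_amp <- ev_target <- numeric(0)

  pos <- c(0, 0)
  heading <- runif(1, 0, 2 * pi)
  # leg durations have a 0.25 s floor so no 100 ms span sees two turns
  # (which could fold the path inside the dispersion criterion)
  draw_leg <- function()
    0.25 + stats::rexp(1, 1 / max(truth$wander_segment_s - 0.25, 0.05))
  state <- "fix"
  regime <- function(i) if (flags[i] == 1L) "present" else "absent"
  mode_start <- 0
  mode_end <- rgamma_mean(1, truth$fix_dur_ms[[regime(1)]],
                          truth$fix_dur_shape) / 1000
  centroid <- pos
  cur_target <- flags[1]
  prev_centroid <- NULL
  wander_from <- NULL

  close_event <- function(i, t_now) {
    # record the event that just ended at t_now
    if (state == "fix") {
      ev_type <<- c(ev_type, "fixation")
      ev_cx <<- c(ev_cx, centroid[1]); ev_cy <<- c(ev_cy, centroid[2])
      ev_amp <<- c(ev_amp, NA_real_)
    } else {
      ev_type <<- c(ev_type, "exploration")
      ev_cx <<- c(ev_cx, NA_real_); ev_cy <<- c(ev_cy, NA_real_)
      ev_amp <<- c(ev_amp, NA_real_)  # filled once the next centroid is known
    }
    ev_start <<- c(ev_start, mode_start); ev_end <<- c(ev_end, t_now)
    ev_target <<- c(ev_target, cur_target)
  }

  for (i in seq_len(n)) {
    t_now <- ts[i]
    while (t_now >= mode_end - 1e-12) {
      close_event(i, mode_end)
      mode_start <- mode_end
      if (state == "fix") {
        state <- "wander"
        cur_target <- flags[i]
        reg <- regime(i)
        prev_centroid <- centroid
        if (jump_mode) {
          mode_end <- mode_start + dt
          pos <- clip(rnorm(2, 0, truth$landing_sd_deg[[reg]]), -b, b)
        } else {
          mode_end <- mode_start +
            max(dt, rgamma_mean(1, truth$wander_dur_s[[reg]],
                                truth$wander_dur_shape))
          wander_from <- centroid
          heading <- runif(1, 0, 2 * pi)
          seg_end <- mode_start + draw_leg()
        }
      } else {
        state <- "fix"
        cur_target <- flags[i]
        centroid <- pos
        # amplitude of the exploration event that just closed
        k <- length(ev_amp)
        if (k > 0 && ev_type[k] == "exploration" && !is.null(prev_centroid))
          ev_amp[k] <- sqrt(sum((centroid - prev_centroid)^2))
        mode_end <- mode_start +
          rgamma_mean(1, truth$fix_dur_ms[[regime(i)]],
                      truth$fix_dur_shape) / 1000
      }
    }
    if (state == "fix") {
      p <- centroid + rnorm(2, 0, truth$jitter_sd_deg)
      x[i] <- p[1]; y[i] <- p[2]
      pos <- centroid
    } else if (jump_mode) {
      x[i] <- pos[1]; y[i] <- pos[2]
    } else {
      # piecewise-straight exploration: constant heading within a leg,
      # 30-120 degree turns between legs (never a dwell or full reversal)
      if (t_now >= seg_end) {
        heading <- heading +
          sample(c(-1, 1), 1) * runif(1, pi / 6, 2 * pi / 3)
        seg_end <- t_now + draw_leg()
      }
      step <- truth$drift_speed_deg_s * dt
      cand <- pos + step * c(cos(heading), sin(heading))
      if (abs(cand[1]) > b) heading <- pi - heading
      if (abs(cand[2]) > b) heading <- -heading
      pos <- clip(pos + step * c(cos(heading), sin(heading)), -b, b)
      x[i] <- pos[1]; y[i] <- pos[2]
    }
  }
  close_event(n, min(mode_end, dur))

  # blink / closure intervals (merged into a disjoint union)
  n_short <- rpois(1, truth$blink_rate_per_min * dur / 60)
  n_long <- rpois(1, truth$long_closure_rate_per_min * dur / 60)
  bs <- c(runif(n_short, 0, dur), runif(n_long, 0, dur))
  bd <- c(runif(n_short, 0.08, 0.30), runif(n_long, 0.6, 1.5))
  blinks <- data.frame(start = numeric(0), end = numeric(0))
  if (length(bs) > 0) {
    o <- order(bs)
    bs <- bs[o]; be <- pmin(bs + bd[o], dur)
    ms <- bs[1]; me <- be[1]
    for (k in seq_along(bs)[-1]) {
      if (bs[k] <= me) me <- max(me, be[k])
      else { blinks <- rbind(blinks, data.frame(start = ms, end = me))
             ms <- bs[k]; me <- be[k] }
    }
    blinks <- rbind(blinks, data.frame(start = ms, end = me))
  }
  valid <- rep(TRUE, n)
  for (k in seq_len(nrow(blinks)))
    valid[ts >= blinks$start[k] & ts <= blinks$end[k]] <- FALSE

  events <- data.frame(type = ev_type, start = ev_start, end = ev_end,
                       cx = ev_cx, cy = ev_cy, amplitude = ev_amp,
                       target = ev_target)
  events$duration_ms <- (events$end - events$start) * 1000
  samples <- data.frame(participant_id = participant, video = video,
                        t = ts, x = x, y = y, valid = valid,
                        target = flags)
  list(samples = samples, events = events, blinks = blinks)
}

#' Simulate gaze traces for a whole study
#'
#' Calls [simulate_gaze()] for every participant x video cell of the design,
#' deriving a distinct sub-seed per cell from `seed`.
#'
#' @inheritParams simulate_gaze
#' @param seed base integer seed.
#' @return A list with `samples` (all traces row-bound) and `truth` (a list
#'   of per-trace ground-truth lists, named `p<participant>_v<video>`).
#' @export
simulate_gaze_study <- function(design, truth = gaze_truth_params(),
                                seed = design$seed) {
  out <- list(); gt <- list()
  for (p in seq_len(design$n_participants)) {
    for (v in seq_len(design$n_videos)) {
      g <- simulate_gaze(design, truth, participant = p, video = v,
                         seed = (seed + 7919L * p + 104729L * v) %% .Machine$integer.max)
      out[[length(out) + 1L]] <- g$samples
      gt[[sprintf("p%d_v%d", p, v)]] <- g[c("events", "blinks")]
    }
  }
  list(samples = do.call(rbind, out), truth = gt)
}
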