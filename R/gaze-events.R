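#' Resample a gaze trace to a uniform rate
#'
#' Linear interpolation of x and y onto a uniform grid (default 60 Hz)
#' spanning the input time range. A resampled point is valid only when both
#' bracketing input samples are valid.
#'
#' @param samples data.frame with columns `t, x, y, valid` (seconds,
#'   degrees, degrees, logical); timestamps strictly increasing.
#' @param rate_hz target rate (default 60).
#' @return A data.frame `t, x, y, valid` on the uniform grid; other columns
#'   of the input (constant per trace, e.g. identifiers) are carried over,
#'   and a per-sample `target` flag is re-sampled by nearest neighbour.
#' @export
resample_gaze <- function(samples, rate_hz = 60) {
  if (nrow(samples) < 2) stop("need at least 2 samples", call. = FALSE)
  if (any(diff(samples$t) <= 0))
    stop("timestamps must be strictly increasing", call. = FALSE)
  grid <- seq(samples$t[1], samples$t[nrow(samples)], by = 1 / rate_hz)
  x <- approx(samples$t, samples$x, grid)$y
  y <- approx(samples$t, samples$y, grid)$y
  vleft <- approx(samples$t, as.numeric(samples$valid), grid,
                  method = "constant", f = 0)$y
  vright <- approx(samples$t, as.numeric(samples$valid), grid,
                   method = "constant", f = 1)$y
  out <- data.frame(t = grid, x = x, y = y,
                    valid = (vleft > 0) & (vright > 0))
  if ("target" %in% names(samples)) {
    idx <- pmax(1, pmin(nrow(samples),
                        round(approx(samples$t, seq_len(nrow(samples)),
                                     grid)$y)))
    out$target <- samples$target[idx]
  }
  for (cn in setdiff(names(samples), c("t", "x", "y", "valid", "target")))
    if (length(unique(samples[[cn]])) == 1) out[[cn]] <- samples[[cn]][1]
  out
}

#' Remove long eye-closure gaps from a gaze trace
#'
#' Runs of consecutive invalid samples longer than `max_closed_frames`
#' (strictly more) are deleted; shorter runs are retained, with x and y
#' linearly interpolated from the flanking valid samples and the samples
#' marked valid. Leading or trailing invalid runs have no flanking valid
#' samples and are always dropped.
#'
#' @param samples data.frame with `t, x, y, valid` at a uniform rate.
#' @param max_closed_frames longest retained closure run (default 20
#'   frames, i.e. 0.33 s at 60 Hz).
#' @return The cleaned data.frame (possibly fewer rows).
#' @export
remove_closure_gaps <- function(samples, max_closed_frames = 20) {
  n <- nrow(samples)
  if (n == 0 || all(samples$valid)) return(samples)
  r <- rle(samples$valid)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  drop <- rep(FALSE, n)
  interp <- rep(FALSE, n)
  for (k in seq_along(r$lengths)) {
    if (r$values[k]) next
    idx <- starts[k]:ends[k]
    if (r$lengths[k] > max_closed_frames || k == 1 || k == length(r$lengths))
      drop[idx] <- TRUE
    else interp[idx] <- TRUE
  }
  if (any(interp)) {
    ok <- samples$valid
    samples$x[interp] <- approx(samples$t[ok], samples$x[ok],
                                samples$t[interp])$y
    samples$y[interp] <- approx(samples$t[ok], samples$y[ok],
                                samples$t[interp])$y
    samples$valid[interp] <- TRUE
  }
  samples[!drop, , drop = FALSE]
}

#' Detect fixations and saccades with the I-DT dispersion algorithm
#'
#' Dispersion-threshold identification: a window is grown over consecutive
#' samples while its dispersion, `(max x - min x) + (max y - min y)`, stays
#' within `max_dispersion_deg`; windows spanning at least `min_duration_ms`
#' (inclusive) are emitted as fixations with their centroid. Inter-fixation
#' intervals become saccade events whose amplitude is the Euclidean
#' distance between the flanking fixation centroids. Traces are split into
#' contiguous segments wherever consecutive timestamps are further apart
#' than `max_gap_s` (gaps left by closure removal); fixations and saccades
#' never span a segment boundary.
#'
#' @param samples data.frame `t, x, y` (uniform rate, gap-cleaned).
#' @param min_duration_ms minimal fixation duration (default 100, inclusive).
#' @param max_dispersion_deg dispersion threshold (default 2).
#' @param max_gap_s timestamp gap splitting the trace into segments
#'   (default 0.1 s).
#' @return A list with `fixations` (`start, end, cx, cy, duration_ms`) and
#'   `saccades` (`start, end, amplitude, duration_s`; degenerate
#'   back-to-back intervals get one sample period).
#' @examples
#' tr <- data.frame(t = (0:30) / 60, x = c(rep(0, 15), rep(10, 16)), y = 0)
#' detect_fixations(tr)
#' @export
detect_fixations <- function(samples, min_duration_ms = 100,
                             max_dispersion_deg = 2, max_gap_s = 0.1) {
  empty_fix <- data.frame(start = numeric(0), end = numeric(0),
                          cx = numeric(0), cy = numeric(0),
                          duration_ms = numeric(0))
  empty_sac <- data.frame(start = numeric(0), end = numeric(0),
                          amplitude = numeric(0), duration_s = numeric(0))
  if (nrow(samples) == 0) return(list(fixations = empty_fix,
                                      saccades = empty_sac))
  if (any(diff(samples$t) <= 0))
    stop("timestamps must be strictly increasing", call. = FALSE)
  dt_med <- median(diff(samples$t))
  seg_id <- cumsum(c(1, diff(samples$t) > max_gap_s))
  fixations <- list(); saccades <- list()
  for (s in unique(seg_id)) {
    seg <- samples[seg_id == s, , drop = FALSE]
    win <- cpp_idt(seg$t, seg$x, seg$y, min_duration_ms / 1000,
                   max_dispersion_deg)
    if (nrow(win) == 0) next
    fx <- data.frame(
      start = seg$t[win[, "start"]],
      end = seg$t[win[, "end"]],
      cx = vapply(seq_len(nrow(win)), function(k)
        mean(seg$x[win[k, "start"]:win[k, "end"]]), 0),
      cy = vapply(seq_len(nrow(win)), function(k)
        mean(seg$y[win[k, "start"]:win[k, "end"]]), 0))
    fx$duration_ms <- (fx$end - fx$start) * 1000
    fixations[[length(fixations) + 1L]] <- fx
    if (nrow(fx) > 1) {
      sc <- data.frame(start = fx$end[-nrow(fx)], end = fx$start[-1])
      sc$amplitude <- sqrt(diff(fx$cx)^2 + diff(fx$cy)^2)
      sc$duration_s <- pmax(sc$end - sc$start, dt_med)
      saccades[[length(saccades) + 1L]] <- sc
    }
  }
  list(fixations = if (length(fixations)) do.call(rbind, fixations)
                   else empty_fix,
       saccades = if (length(saccades)) do.call(rbind, saccades)
                  else empty_sac)
}

# prefix-sum overlap helpers: events sorted by start (non-overlapping)
overlap_time <- function(starts, ends, lo, hi) {
  # integral over [lo, hi] of the event-indicator, via the cumulative
  # event-time function F evaluated with findInterval
  if (length(starts) == 0) return(numeric(length(lo)))
  knots <- as.vector(rbind(starts, ends))
  vals <- cumsum(as.vector(rbind(rep(0, length(starts)), ends - starts)))
  cumvals <- c(0, vals)
  Fat <- function(u) {
    i <- findInterval(u, knots)
    base <- cumvals[i + 1]
    inside <- i >= 1 & i %% 2 == 1  # u inside event (i odd)
    add <- ifelse(inside, u - knots[pmax(i, 1)], 0)
    # cumvals at odd i counts full events before this one
    base2 <- ifelse(inside, cumvals[pmax(i, 1)], base)
    base2 + add
  }
  Fat(hi) - Fat(lo)
}

count_overlapping <- function(starts, ends, lo, hi) {
  if (length(starts) == 0) return(integer(length(lo)))
  # events with start < hi minus events with end <= lo
  findInterval(hi, starts, left.open = TRUE) -
    findInterval(lo, ends, left.open = FALSE)
}

sum_overlapping <- function(values, starts, ends, lo, hi) {
  if (length(starts) == 0) return(numeric(length(lo)))
  cs <- c(0, cumsum(values))
  cs[findInterval(hi, starts, left.open = TRUE) + 1] -
    cs[findInterval(lo, ends, left.open = FALSE) + 1]
}

#' Sliding-window oculomotor features
#'
#' For every time `t` on a step grid, events overlapping the window
#' `[t - window_s/2, t + window_s/2]` (truncated at the trace boundaries)
#' are aggregated into four features: fixation duration in ms per second of
#' window coverage, number of fixations per second, mean saccade amplitude
#' in degrees (`NA` when the window holds no saccade), and the
#' fixation/saccade ratio — total fixation time divided by total saccade
#' time in the window (`NA` when the window holds no saccade time).
#'
#' @param fixations,saccades event tables from [detect_fixations()].
#' @param samples the gap-cleaned sample table (`t` and `target` are used
#'   for the grid range and the per-window target flag).
#' @param window_s window length in seconds (default 60).
#' @param step_s step of the feature grid (default 1/60 s).
#' @return A data.frame `t, fix_dur_ms_per_s, n_fix_per_s, sacc_amp_deg,
#'   fix_sacc_ratio, target`.
#' @export
sliding_window_features <- function(fixations, saccades, samples,
                                    window_s = 60, step_s = 1 / 60) {
  if (window_s <= 0) stop("'window_s' must be positive", call. = FALSE)
  if (nrow(samples) == 0)
    return(data.frame(t = numeric(0), fix_dur_ms_per_s = numeric(0),
                      n_fix_per_s = numeric(0), sacc_amp_deg = numeric(0),
                      fix_sacc_ratio = numeric(0), target = integer(0)))
  t0 <- samples$t[1]; t1 <- samples$t[nrow(samples)]
  grid <- seq(t0, t1, by = step_s)
  lo <- pmax(grid - window_s / 2, t0)
  hi <- pmin(grid + window_s / 2, t1)
  cover <- pmax(hi - lo, .Machine$double.eps)

  fix_time <- overlap_time(fixations$start, fixations$end, lo, hi)
  n_fix <- count_overlapping(fixations$start, fixations$end, lo, hi)
  # saccade time uses effective durations (degenerate intervals already
  # widened to one sample period in detect_fixations)
  if (nrow(saccades) > 0) {
    sac_end_eff <- saccades$start + saccades$duration_s
    sac_time <- overlap_time(saccades$start, sac_end_eff, lo, hi)
    amp_sum <- sum_overlapping(saccades$amplitude, saccades$start,
                               saccades$end, lo, hi)
    n_sac <- count_overlapping(saccades$start, saccades$end, lo, hi)
  } else {
    sac_time <- numeric(length(grid))
    amp_sum <- numeric(length(grid))
    n_sac <- integer(length(grid))
  }
  tgt <- if ("target" %in% names(samples)) {
    idx <- pmax(1, pmin(nrow(samples),
                        round(approx(samples$t, seq_len(nrow(samples)),
                                     grid, rule = 2)$y)))
    samples$target[idx]
  } else rep(0L, length(grid))

  data.frame(
    t = grid,
    fix_dur_ms_per_s = 1000 * fix_time / cover,
    n_fix_per_s = n_fix / cover,
    sacc_amp_deg = ifelse(n_sac > 0, amp_sum / n_sac, NA_real_),
    fix_sacc_ratio = ifelse(sac_time > 0, fix_time / sac_time, NA_real_),
    target = tgt)
}

#' Full gaze pipeline: samples to windowed features, per trace
#'
#' Convenience wrapper running [resample_gaze()], [remove_closure_gaps()],
#' [detect_fixations()] and [sliding_window_features()] for every
#' participant x video trace in a combined sample table.
#'
#' @param samples combined table with `participant_id, video, t, x, y,
#'   valid, target`.
#' @param rate_hz,max_closed_frames,min_duration_ms,max_dispersion_deg,window_s,step_s
#'   stage parameters (see the stage functions).
#' @return A feature table with `participant_id` and `video` columns added.
#' @export
extract_gaze_features <- function(samples, rate_hz = 60,
                                  max_closed_frames = 20,
                                  min_duration_ms = 100,
                                  max_dispersion_deg = 2,
                                  window_s = 60, step_s = 1 / 60) {
  pieces <- split(samples,
                  list(samples$participant_id, samples$video), drop = TRUE)
  out <- lapply(pieces, function(tr) {
    tr <- tr[order(tr$t), , drop = FALSE]
    tr <- resample_gaze(tr, rate_hz)
    tr <- remove_closure_gaps(tr, max_closed_frames)
    if (nrow(tr) < 2) return(NULL)
    ev <- detect_fixations(tr, min_duration_ms, max_dispersion_deg)
    ft <- sliding_window_features(ev$fixations, ev$saccades, tr,
                                  window_s, step_s)
    ft$participant_id <- tr$participant_id[1]
    ft$video <- tr$video[1]
    ft
  })
  do.call(rbind, c(out[!vapply(out, is.null, TRUE)],
                   list(make.row.names = FALSE)))
}
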