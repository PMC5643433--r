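#' Two-minute medians of raw vital-sign streams
#'
#' Bins each participant's records into contiguous `interval_s` bins
#' `(k-1, k] * interval_s` and outputs, per bin, the median of the samples
#' in the preceding interval (standard midpoint convention for even
#' counts). Bins without samples emit missing values.
#'
#' @param records data.frame `participant_id, t, hf, map, rf, spo2`,
#'   timestamps sorted within participant.
#' @param interval_s aggregation interval in seconds (default 120).
#' @param t_max end of the covered period; defaults to the last timestamp.
#' @return A data.frame `participant_id, t, bin` with per-signal medians;
#'   `t` is the bin end.
#' @export
two_minute_medians <- function(records, interval_s = 120, t_max = NULL) {
  sig <- intersect(c("hf", "map", "rf", "spo2"), names(records))
  if (is.null(t_max)) t_max <- max(records$t)
  n_bins <- ceiling(t_max / interval_s)
  out <- list()
  for (p in unique(records$participant_id)) {
    rp <- records[records$participant_id == p, , drop = FALSE]
    if (is.unsorted(rp$t)) stop("timestamps must be sorted per participant",
                                call. = FALSE)
    bin <- ceiling(rp$t / interval_s)
    bin[rp$t <= 0] <- 1L
    o <- data.frame(participant_id = p, bin = seq_len(n_bins),
                    t = seq_len(n_bins) * interval_s)
    for (s in sig)
      o[[s]] <- vapply(seq_len(n_bins), function(k) {
        v <- rp[[s]][bin == k]
        if (length(v) == 0) NA_real_ else median(v, na.rm = TRUE)
      }, 0)
    out[[length(out) + 1L]] <- o
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Map vital-sign medians onto the begin/middle/end analysis grid
#'
#' For each video, the median record nearest in time to the video's start,
#' midpoint and end is assigned to the `begin`, `middle` and `end`
#' positions (ties broken toward the earlier record). Only records whose
#' timestamp falls within the video's time span are candidates, so no
#' analysis point borrows a record from a different video. Videos with no
#' available medians yield missing values for all three positions.
#'
#' @param medians output of [two_minute_medians()] (or any table
#'   `participant_id, t` plus signal columns).
#' @param video_schedule data.frame `video_index, start_s, end_s`, one row
#'   per video (three videos in the reference design).
#' @return A data.frame `participant_id, video_index, position, time_index`
#'   plus signal columns, with `time_index = 3 * (video_index - 1) +
#'   position rank` (begin = 1, middle = 2, end = 3).
#' @examples
#' med <- data.frame(participant_id = 1, t = c(120, 240), map = c(90, 88))
#' sched <- data.frame(video_index = 1, start_s = 0, end_s = 300)
#' to_analysis_grid(med, sched)
#' @export
to_analysis_grid <- function(medians, video_schedule) {
  sig <- intersect(c("hf", "map", "rf", "spo2"), names(medians))
  positions <- c("begin", "middle", "end")
  out <- list()
  for (p in unique(medians$participant_id)) {
    mp <- medians[medians$participant_id == p, , drop = FALSE]
    for (v in seq_len(nrow(video_schedule))) {
      vs <- video_schedule$start_s[v]; ve <- video_schedule$end_s[v]
      vi <- video_schedule$video_index[v]
      # nearest assignment is over bins in the video's span; empty bins
      # (all-NA medians) propagate their missingness to the analysis point
      cand <- mp[mp$t >= vs & mp$t <= ve, , drop = FALSE]
      targets <- c(vs, (vs + ve) / 2, ve)
      for (k in 1:3) {
        row <- data.frame(participant_id = p, video_index = vi,
                          position = positions[k],
                          time_index = 3L * (vi - 1L) + k)
        if (nrow(cand) == 0) {
          for (s in sig) row[[s]] <- NA_real_
        } else {
          d <- abs(cand$t - targets[k])
          j <- which(d == min(d))[1]  # ties toward the earlier record
          for (s in sig) row[[s]] <- cand[[s]][j]
        }
        out[[length(out) + 1L]] <- row
      }
    }
  }
  res <- do.call(rbind, c(out, list(make.row.names = FALSE)))
  n_missing <- sum(!stats::complete.cases(res[sig]))
  if (n_missing > 0)
    message(sprintf("to_analysis_grid: %d analysis point(s) missing", n_missing))
  res
}
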