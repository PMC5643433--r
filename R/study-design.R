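#' Study design for a VR stimulation session
#'
#' Describes the stimulation protocol that the synthetic-data generators
#' emulate: a number of participants each watching `n_videos` nature videos
#' of `video_duration` seconds through a head-mounted display, with a visual
#' target superimposed at the beginning, the middle and the end of every
#' video, 60 Hz gaze recording, and vital signs aggregated every
#' `vital_interval` seconds.
#'
#' @param n_participants number of participants (default 37).
#' @param n_videos number of videos per participant (default 3).
#' @param video_duration duration of each video in seconds (default 300).
#' @param target_epochs list with one `k x 2` matrix per video giving
#'   `(start_s, end_s)` of target-present epochs in video-local seconds.
#'   The default places a 20 s epoch at the beginning, middle and end of
#'   each video (scaled for shorter videos). Epochs must be disjoint,
#'   ordered, and inside `[0, video_duration]`.
#' @param gaze_rate gaze sampling rate in Hz (default 60).
#' @param vital_interval vital-sign aggregation interval in seconds
#'   (default 120, i.e. two-minute medians).
#' @param seed integer seed used by generators that take this design.
#'
#' @return An object of class `icuvr_design` (a validated list).
#' @examples
#' d <- study_design(n_participants = 4, video_duration = 60)
#' d$target_epochs[[1]]
#' @export
study_design <- function(n_participants = 37, n_videos = 3,
                         video_duration = 300, target_epochs = NULL,
                         gaze_rate = 60, vital_interval = 120, seed = 1L) {
  check_count <- function(v, name) {
    if (length(v) != 1 || !is.finite(v) || v <= 0)
      stop(sprintf("'%s' must be a positive number", name), call. = FALSE)
  }
  check_count(n_participants, "n_participants")
  check_count(n_videos, "n_videos")
  check_count(video_duration, "video_duration")
  check_count(gaze_rate, "gaze_rate")
  check_count(vital_interval, "vital_interval")

  if (is.null(target_epochs)) {
    len <- video_duration / 15          # 20 s for a 300 s video
    mid <- video_duration / 2
    ep <- rbind(c(len / 2, 3 * len / 2),
                c(mid - len / 2, mid + len / 2),
                c(video_duration - 3 * len / 2, video_duration - len / 2))
    colnames(ep) <- c("start_s", "end_s")
    target_epochs <- rep(list(ep), n_videos)
  }
  if (length(target_epochs) != n_videos)
    stop("'target_epochs' must have one entry per video", call. = FALSE)
  for (v in seq_along(target_epochs)) {
    ep <- target_epochs[[v]]
    if (is.null(dim(ep))) ep <- matrix(ep, ncol = 2)
    if (ncol(ep) != 2)
      stop("'target_epochs' entries must be (start_s, end_s) matrices",
           call. = FALSE)
    if (any(ep < 0) || any(ep > video_duration))
      stop("'target_epochs' must lie inside [0, video_duration]",
           call. = FALSE)
    if (nrow(ep) > 1) {
      if (any(diff(as.vector(t(ep))) < 0))
        stop("'target_epochs' must be disjoint and ordered", call. = FALSE)
    }
    if (any(ep[, 2] <= ep[, 1]))
      stop("'target_epochs' must have end_s > start_s", call. = FALSE)
    colnames(ep) <- c("start_s", "end_s")
    target_epochs[[v]] <- ep
  }
  structure(list(n_participants = as.integer(n_participants),
                 n_videos = as.integer(n_videos),
                 video_duration = video_duration,
                 target_epochs = target_epochs,
                 gaze_rate = gaze_rate,
                 vital_interval = vital_interval,
                 seed = as.integer(seed)),
            class = "icuvr_design")
}

#' @export
print.icuvr_design <- function(x, ...) {
  cat(sprintf(
    "VR stimulation design: %d participants, %d video(s) x %g s, %g Hz gaze, vitals every %g s\n",
    x$n_participants, x$n_videos, x$video_duration, x$gaze_rate,
    x$vital_interval))
  invisible(x)
}

# target flag (0/1) for video-local times, given a design and video index
target_flag_at <- function(design, video, t) {
  ep <- design$target_epochs[[video]]
  flag <- rep(0L, length(t))
  for (k in seq_len(nrow(ep)))
    flag[t >= ep[k, 1] & t <= ep[k, 2]] <- 1L
  flag
}
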