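#' Simulate grayscale eye-camera frames with ground truth
#'
#' Open-eye frames contain a dark circular pupil disc on a brighter
#' background; eyes-closed frames contain a uniform lid texture and no
#' disc. Additive Gaussian noise with SD `noise_sd` is applied to every
#' frame and intensities are clipped to `[0, 255]`.
#'
#' @param n_frames number of frames to generate.
#' @param pupil_center_px numeric `(x, y)` centre of the pupil in pixels
#'   (x = column, y = row, 1-based).
#' @param pupil_radius_px pupil radius in pixels (>= 3); the disc must lie
#'   fully inside the frame.
#' @param closure_frames integer indices of eyes-closed frames.
#' @param image_size_px integer `(width, height)` of the frames.
#' @param noise_sd SD of the additive intensity noise (8-bit units).
#' @param pupil_intensity,background_intensity,lid_intensity 8-bit levels of
#'   the disc, the open-eye background and the closed lid.
#' @param seed integer seed.
#'
#' @return A list with `frames` (list of `height x width` matrices, values
#'   in `[0, 255]`) and `truth` (data.frame `frame_index, closed, cx, cy,
#'   r`).
#' @examples
#' fr <- simulate_eye_frames(2, c(40, 30), 12, closure_frames = 2,
#'                           image_size_px = c(80, 60), noise_sd = 0)
#' fr$truth
#' @export
simulate_eye_frames <- function(n_frames, pupil_center_px = c(60, 60),
                                pupil_radius_px = 25,
                                closure_frames = integer(0),
                                image_size_px = c(120, 120), noise_sd = 5,
                                pupil_intensity = 40,
                                background_intensity = 170,
                                lid_intensity = 150, seed = 1L) {
  if (n_frames < 1) stop("'n_frames' must be positive", call. = FALSE)
  if (pupil_radius_px < 3)
    stop("'pupil_radius_px' must be at least 3 px", call. = FALSE)
  w <- image_size_px[1]; h <- image_size_px[2]
  cx <- pupil_center_px[1]; cy <- pupil_center_px[2]
  if (cx - pupil_radius_px < 1 || cx + pupil_radius_px > w ||
      cy - pupil_radius_px < 1 || cy + pupil_radius_px > h)
    stop("'pupil_center_px': pupil disc must lie fully inside the frame",
         call. = FALSE)
  set.seed(as.integer(seed))
  xs <- matrix(rep(seq_len(w), each = h), nrow = h)   # x = column index
  ys <- matrix(rep(seq_len(h), times = w), nrow = h)  # y = row index
  disc <- (xs - cx)^2 + (ys - cy)^2 <= pupil_radius_px^2
  frames <- vector("list", n_frames)
  closed <- seq_len(n_frames) %in% closure_frames
  for (k in seq_len(n_frames)) {
    if (closed[k]) {
      img <- matrix(lid_intensity, h, w)
    } else {
      img <- matrix(background_intensity, h, w)
      img[disc] <- pupil_intensity
    }
    if (noise_sd > 0) img <- img + matrix(rnorm(h * w, 0, noise_sd), h, w)
    frames[[k]] <- clip(img, 0, 255)
  }
  truth <- data.frame(frame_index = seq_len(n_frames), closed = closed,
                      cx = ifelse(closed, NA_real_, cx),
                      cy = ifelse(closed, NA_real_, cy),
                      r = ifelse(closed, NA_real_, pupil_radius_px))
  list(frames = frames, truth = truth)
}

#' Write / read eye frames as 8-bit grayscale PNG files
#'
#' @param frames list of intensity matrices in `[0, 255]`.
#' @param dir directory for `frame_%04d.png` files (created if needed).
#' @return `write_eye_frames` returns the file paths invisibly;
#'   `read_eye_frames` returns a list of matrices in `[0, 255]`.
#' @export
write_eye_frames <- function(frames, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, sprintf("frame_%04d.png", seq_along(frames)))
  for (k in seq_along(frames))
    png::writePNG(frames[[k]] / 255, paths[k])
  invisible(paths)
}

#' @rdname write_eye_frames
#' @export
read_eye_frames <- function(dir) {
  paths <- sort(list.files(dir, pattern = "\\.png$", full.names = TRUE))
  lapply(paths, function(p) {
    m <- png::readPNG(p)
    if (length(dim(m)) == 3) m <- m[, , 1]
    m * 255
  })
}
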