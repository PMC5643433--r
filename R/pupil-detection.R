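#' Pupil-detection configuration
#'
#' Parameters of the frame-processing chain
#' `denoise_frame()` -> `edge_map()` -> `remove_small_objects()` ->
#' `detect_pupil()`. Canny thresholds default to `NULL`, meaning they are
#' derived per frame from the gradient-magnitude histogram by Otsu's method
#' (`high = otsu(magnitude)`, `low = 0.4 * high`).
#'
#' @param gaussian_sigma SD of the Gaussian denoising filter (px).
#' @param median_size side of the square median filter window (px).
#' @param canny_low,canny_high hysteresis thresholds on gradient magnitude;
#'   `NULL` = Otsu-derived per frame.
#' @param canny_min_gradient absolute floor (8-bit gradient units) for the
#'   Otsu-derived high threshold, so featureless frames (closed lids) do
#'   not promote sensor noise to edges.
#' @param min_object_px connected components (8-connectivity) with fewer
#'   pixels than this are removed from the edge map; components with
#'   exactly this many pixels are retained.
#' @param radius_range_px `(min, max)` candidate pupil radii in px.
#' @param radius_step_px spacing of the candidate radius grid.
#' @param score_threshold a circle is accepted when its Hough score (votes
#'   normalised by the circle circumference, so a perfect ring scores about
#'   1) reaches this fraction of the perfect-circle score.
#' @return A list of class `icuvr_pupil_config`.
#' @export
pupil_config <- function(gaussian_sigma = 0.5, median_size = 8,
                         canny_low = NULL, canny_high = NULL,
                         canny_min_gradient = 20,
                         min_object_px = 50, radius_range_px = c(10, 80),
                         radius_step_px = 1, score_threshold = 0.3) {
  if (!is.null(canny_low) && !is.null(canny_high) && canny_low >= canny_high)
    stop("'canny_low' must be below 'canny_high'", call. = FALSE)
  if (length(radius_range_px) != 2 || any(radius_range_px <= 0) ||
      radius_range_px[1] > radius_range_px[2])
    stop("'radius_range_px' must be positive and ordered", call. = FALSE)
  structure(list(gaussian_sigma = gaussian_sigma, median_size = median_size,
                 canny_low = canny_low, canny_high = canny_high,
                 canny_min_gradient = canny_min_gradient,
                 min_object_px = min_object_px,
                 radius_range_px = radius_range_px,
                 radius_step_px = radius_step_px,
                 score_threshold = score_threshold),
            class = "icuvr_pupil_config")
}

check_frame <- function(frame) {
  if (!is.matrix(frame) || length(frame) == 0)
    stop("frame must be a non-empty numeric matrix", call. = FALSE)
  if (any(!is.finite(frame)))
    stop("frame contains non-finite intensities", call. = FALSE)
}

#' Denoise an eye frame
#'
#' Gaussian smoothing (default sigma 0.5 px) followed by a square median
#' filter (default 8 x 8 px). Even-sized median windows span offsets
#' `-(s/2 - 1) .. s/2` around the pixel, with replicated borders; even pixel
#' counts take the midpoint of the two central order statistics.
#'
#' @param frame `height x width` intensity matrix in `[0, 255]`.
#' @param gaussian_sigma,median_size filter parameters.
#' @return The denoised frame, same dimensions.
#' @export
denoise_frame <- function(frame, gaussian_sigma = 0.5, median_size = 8) {
  check_frame(frame)
  sm <- frame
  if (gaussian_sigma > 0)
    sm <- EBImage::imageData(EBImage::gblur(frame, sigma = gaussian_sigma))
  if (median_size > 1) sm <- cpp_median_filter(sm, as.integer(median_size))
  sm
}

# Sobel gradients; returns list(gx, gy, mag) with zeroed 1-px border
sobel_gradients <- function(frame) {
  nr <- nrow(frame); nc <- ncol(frame)
  pad <- function(di, dj) {
    ri <- clip(seq_len(nr) + di, 1, nr)
    cj <- clip(seq_len(nc) + dj, 1, nc)
    frame[ri, cj, drop = FALSE]
  }
  gx <- (pad(-1, 1) + 2 * pad(0, 1) + pad(1, 1)) -
        (pad(-1, -1) + 2 * pad(0, -1) + pad(1, -1))
  gy <- (pad(1, -1) + 2 * pad(1, 0) + pad(1, 1)) -
        (pad(-1, -1) + 2 * pad(-1, 0) + pad(-1, 1))
  gx[c(1, nr), ] <- 0; gx[, c(1, nc)] <- 0
  gy[c(1, nr), ] <- 0; gy[, c(1, nc)] <- 0
  list(gx = gx, gy = gy, mag = sqrt(gx^2 + gy^2))
}

#' Canny edge map of an eye frame
#'
#' Sobel gradients, non-maximum suppression along the quantised gradient
#' direction, and hysteresis thresholding (weak-edge components are kept
#' only when 8-connected to a strong edge). When thresholds are `NULL` the
#' high threshold is Otsu's threshold of the gradient-magnitude histogram
#' and the low threshold is 0.4 times that.
#'
#' @inheritParams denoise_frame
#' @param canny_low,canny_high hysteresis thresholds on gradient magnitude.
#' @param min_gradient absolute floor for the Otsu-derived high threshold.
#' @return A logical `height x width` matrix of edge pixels.
#' @export
edge_map <- function(frame, canny_low = NULL, canny_high = NULL,
                     min_gradient = 20) {
  check_frame(frame)
  if (!is.null(canny_low) && !is.null(canny_high) && canny_low >= canny_high)
    stop("'canny_low' must be below 'canny_high'", call. = FALSE)
  g <- sobel_gradients(frame)
  mx <- max(g$mag)
  if (mx <= 0) return(matrix(FALSE, nrow(frame), ncol(frame)))
  if (is.null(canny_high)) {
    canny_high <- max(as.numeric(EBImage::otsu(
      EBImage::Image(g$mag / mx), range = c(0, 1))) * mx, min_gradient)
    if (is.null(canny_low)) canny_low <- 0.4 * canny_high
  }
  if (is.null(canny_low)) canny_low <- 0.4 * canny_high

  # non-maximum suppression along the gradient direction, with the
  # magnitude at p +/- u (u = unit gradient) sampled bilinearly so thinned
  # ridges stay 8-connected
  nr <- nrow(frame); nc <- ncol(frame)
  shift <- function(m, di, dj) {
    out <- matrix(0, nr, nc)
    ri <- seq_len(nr) + di; cj <- seq_len(nc) + dj
    ok_r <- ri >= 1 & ri <= nr; ok_c <- cj >= 1 & cj <= nc
    out[ok_r, ok_c] <- m[ri[ok_r], cj[ok_c], drop = FALSE]
    out
  }
  shifts <- list()
  for (di in -1:1) for (dj in -1:1)
    shifts[[paste(di, dj)]] <- shift(g$mag, di, dj)
  safe_mag <- ifelse(g$mag > 0, g$mag, 1)
  ux <- g$gx / safe_mag; uy <- g$gy / safe_mag
  bilin <- function(ux, uy) {
    sx <- ifelse(ux >= 0, 1L, -1L); sy <- ifelse(uy >= 0, 1L, -1L)
    fx <- abs(ux); fy <- abs(uy)
    pick <- function(di_m, dj_m) {
      out <- matrix(0, nr, nc)
      for (di in sort(unique(as.vector(di_m))))
        for (dj in sort(unique(as.vector(dj_m)))) {
          sel <- di_m == di & dj_m == dj
          out[sel] <- shifts[[paste(di, dj)]][sel]
        }
      out
    }
    zero <- matrix(0L, nr, nc)
    (1 - fx) * (1 - fy) * pick(zero, zero) +
      fx * (1 - fy) * pick(zero, sx) +
      (1 - fx) * fy * pick(sy, zero) +
      fx * fy * pick(sy, sx)
  }
  n1 <- bilin(ux, uy)
  n2 <- bilin(-ux, -uy)
  eps_nms <- 1e-9
  keep <- g$mag > 0 & g$mag >= n1 - eps_nms & g$mag >= n2 - eps_nms
  thin <- g$mag * keep
  strong <- thin >= canny_high
  weak <- thin >= canny_low
  if (!any(strong)) return(matrix(FALSE, nr, nc))
  lab <- cpp_label8(weak)
  keep_labels <- unique(lab[strong])
  weak & matrix(lab %in% keep_labels, nr, nc)
}

#' Remove small connected components from a binary image
#'
#' Components (8-connectivity) with fewer than `min_pixels` pixels are
#' removed; components with exactly `min_pixels` pixels are retained.
#'
#' @param binary logical matrix.
#' @param min_pixels minimum retained component size (default 50).
#' @return Logical matrix of the same dimensions.
#' @export
remove_small_objects <- function(binary, min_pixels = 50) {
  if (!is.matrix(binary)) stop("'binary' must be a matrix", call. = FALSE)
  mode(binary) <- "logical"
  if (!any(binary)) return(binary)
  lab <- cpp_label8(binary)
  sizes <- tabulate(lab[lab > 0])
  small <- which(sizes < min_pixels)
  binary & !matrix(lab %in% small, nrow(binary), ncol(binary))
}

#' Detect the pupil circle in a binary edge image
#'
#' Circular Hough transform over the configured radius grid. The returned
#' score is the accumulator mass near the best centre normalised by the
#' circle circumference, so a complete one-pixel ring scores about 1; the
#' detection is accepted when the score reaches `score_threshold` times
#' the perfect-circle score.
#'
#' @param binary logical edge matrix.
#' @param radius_range_px `(min, max)` candidate radii in px.
#' @param radius_step_px candidate radius spacing.
#' @param score_threshold acceptance fraction of the perfect-circle score.
#' @return A list `(found, cx, cy, r, score)`; `cx, cy, r` are `NA` when
#'   not found.
#' @export
detect_pupil <- function(binary, radius_range_px = c(10, 80),
                         radius_step_px = 1, score_threshold = 0.3) {
  if (!is.matrix(binary)) stop("'binary' must be a matrix", call. = FALSE)
  if (length(radius_range_px) != 2 || any(radius_range_px <= 0) ||
      radius_range_px[1] > radius_range_px[2])
    stop("'radius_range_px' must be positive and ordered", call. = FALSE)
  mode(binary) <- "logical"
  idx <- which(binary, arr.ind = TRUE)
  empty <- list(found = FALSE, cx = NA_real_, cy = NA_real_, r = NA_real_,
                score = 0)
  if (nrow(idx) == 0) return(empty)
  radii <- seq(radius_range_px[1], radius_range_px[2], by = radius_step_px)
  res <- cpp_hough_circle(as.integer(idx[, 2]), as.integer(idx[, 1]),
                          ncol(binary), nrow(binary), radii)
  if (!is.finite(res$score) || res$score < score_threshold) {
    empty$score <- max(0, res$score)
    return(empty)
  }
  list(found = TRUE, cx = res$cx, cy = res$cy, r = res$r, score = res$score)
}

#' Classify a frame as eyes-closed
#'
#' Runs the full chain (denoise, Canny edges, small-object removal, Hough
#' pupil detection); the frame is closed exactly when no pupil circle is
#' found.
#'
#' @param frame intensity matrix in `[0, 255]`.
#' @param config a [pupil_config()] object.
#' @return `TRUE` if closed (no pupil detected).
#' @export
classify_closure <- function(frame, config = pupil_config()) {
  !process_frame(frame, config)$found
}

# full chain on one frame
process_frame <- function(frame, config = pupil_config()) {
  den <- denoise_frame(frame, config$gaussian_sigma, config$median_size)
  edges <- edge_map(den, config$canny_low, config$canny_high,
                    config$canny_min_gradient)
  edges <- remove_small_objects(edges, config$min_object_px)
  detect_pupil(edges, config$radius_range_px, config$radius_step_px,
               config$score_threshold)
}

#' Run pupil detection over a sequence of frames
#'
#' @param frames list of intensity matrices.
#' @param config a [pupil_config()] object.
#' @return A data.frame `frame_index, closed, cx, cy, r, score`.
#' @examples
#' fr <- simulate_eye_frames(2, c(40, 30), 12, closure_frames = 2,
#'                           image_size_px = c(80, 60), noise_sd = 2)
#' detect_pupils(fr$frames, pupil_config(radius_range_px = c(6, 20)))
#' @export
detect_pupils <- function(frames, config = pupil_config()) {
  rows <- lapply(seq_along(frames), function(k) {
    d <- process_frame(frames[[k]], config)
    data.frame(frame_index = k, closed = !d$found, cx = d$cx, cy = d$cy,
               r = d$r, score = d$score)
  })
  do.call(rbind, rows)
}
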