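#' Bounding-box tables
#'
#' Boxes use the image convention throughout: origin at the top-left corner
#' of the frame, x increasing rightward, y increasing downward, continuous
#' (not integer-snapped) pixel units. A box is stored by its top-left corner
#' plus width and height, with an optional detector confidence in \[0, 1\].
#' A collection of boxes is a plain `data.frame` with columns
#' `x`, `y`, `w`, `h`, `conf`.
#'
#' @param x,y Top-left corner coordinates in pixels.
#' @param w,h Box width and height in pixels; must be strictly positive.
#' @param conf Detector confidence in \[0, 1\]; `NA` when not applicable
#'   (e.g. ground-truth boxes).
#' @return A `data.frame` with columns `x`, `y`, `w`, `h`, `conf`.
#' @examples
#' b <- boxes(x = c(0, 100), y = c(0, 50), w = c(10, 40), h = c(10, 80),
#'            conf = c(0.9, 0.6))
#' box_bottom(b)
#' @export
boxes <- function(x = numeric(), y = numeric(), w = numeric(),
                  h = numeric(), conf = NULL) {
  n <- length(x)
  if (is.null(conf)) conf <- rep(NA_real_, n)
  df <- data.frame(x = as.numeric(x), y = as.numeric(y),
                   w = as.numeric(w), h = as.numeric(h),
                   conf = as.numeric(conf))
  validate_boxes(df)
}

#' Validate a box table
#'
#' @param df A `data.frame` with at least columns `x`, `y`, `w`, `h`.
#' @return The validated table (columns reordered, `conf` added if missing).
#' @export
validate_boxes <- function(df) {
  if (!is.data.frame(df) || !all(c("x", "y", "w", "h") %in% names(df)))
    stop("boxes must be a data.frame with columns x, y, w, h", call. = FALSE)
  if (!"conf" %in% names(df)) df$conf <- NA_real_
  bad <- !is.finite(df$w) | !is.finite(df$h) | df$w <= 0 | df$h <= 0
  if (any(bad))
    stop("invalid box: width and height must be positive and finite",
         call. = FALSE)
  df[, c("x", "y", "w", "h", "conf")]
}

empty_boxes <- function() boxes()

#' @rdname boxes
#' @param b A box table.
#' @export
box_bottom <- function(b) b$y + b$h

#' @rdname boxes
#' @export
box_center_y <- function(b) b$y + b$h / 2

#' Intersection over union of two boxes
#'
#' Symmetric overlap ratio in \[0, 1\]; 0 for disjoint boxes, 1 only for
#' identical boxes. Used as the association affinity in the tracker and as
#' the spatial overlap measure when matching counted tracks to ground truth.
#'
#' @param a,b Single boxes: one-row box tables (or anything with `$x`, `$y`,
#'   `$w`, `$h` of length 1).
#' @return IoU ratio in \[0, 1\].
#' @examples
#' iou(boxes(0, 0, 10, 10), boxes(5, 0, 10, 10)) # 1/3
#' @export
iou <- function(a, b) {
  a <- validate_boxes(as.data.frame(a[c("x", "y", "w", "h")]))
  b <- validate_boxes(as.data.frame(b[c("x", "y", "w", "h")]))
  ix <- pmax(0, pmin(a$x + a$w, b$x + b$w) - pmax(a$x, b$x))
  iy <- pmax(0, pmin(a$y + a$h, b$y + b$h) - pmax(a$y, b$y))
  inter <- ix * iy
  inter / (a$w * a$h + b$w * b$h - inter)
}

#' Pairwise IoU matrix between two box tables
#'
#' @param a,b Box tables with `nrow(a)` and `nrow(b)` boxes.
#' @return A `nrow(a)` x `nrow(b)` numeric matrix of IoU values.
#' @export
iou_matrix <- function(a, b) {
  na <- nrow(a); nb <- nrow(b)
  m <- matrix(0, na, nb)
  if (na == 0L || nb == 0L) return(m)
  ax1 <- a$x; ax2 <- a$x + a$w; ay1 <- a$y; ay2 <- a$y + a$h
  bx1 <- b$x; bx2 <- b$x + b$w; by1 <- b$y; by2 <- b$y + b$h
  area_a <- a$w * a$h; area_b <- b$w * b$h
  for (j in seq_len(nb)) {
    ix <- pmax(0, pmin(ax2, bx2[j]) - pmax(ax1, bx1[j]))
    iy <- pmax(0, pmin(ay2, by2[j]) - pmax(ay1, by1[j]))
    inter <- ix * iy
    m[, j] <- inter / (area_a + area_b[j] - inter)
  }
  m
}

#' Filter detections by confidence
#'
#' Keeps boxes whose confidence is at or above the threshold (inclusive
#' boundary, the usual detector convention). Boxes with `NA` confidence —
#' e.g. replayed ground truth — are kept. Order is preserved.
#'
#' @param dets A box table.
#' @param threshold Confidence threshold in \[0, 1\]; default 0.5.
#' @return The filtered box table.
#' @export
filter_by_confidence <- function(dets, threshold = 0.5) {
  stopifnot(length(threshold) == 1L, threshold >= 0, threshold <= 1)
  dets <- validate_boxes(dets)
  keep <- is.na(dets$conf) | dets$conf >= threshold
  dets[keep, , drop = FALSE]
}

#' Video metadata
#'
#' The default profile matches the in-trawl stereo camera footage this
#' package targets: 1280 x 720 pixels at 60 frames per second.
#'
#' @param width,height Frame dimensions in pixels.
#' @param fps Native frame rate in frames per second; must be positive.
#' @param n_frames Total number of frames in the stream (>= 0).
#' @return A list of class `video_meta`.
#' @export
video_meta <- function(width = 1280, height = 720, fps = 60, n_frames = 0L) {
  stopifnot(width > 0, height > 0, fps > 0, n_frames >= 0)
  structure(list(width = as.numeric(width), height = as.numeric(height),
                 fps = as.numeric(fps), n_frames = as.integer(n_frames)),
            class = "video_meta")
}

#' @export
print.video_meta <- function(x, ...) {
  cat(sprintf("video: %gx%g @ %g FPS, %d frames\n",
              x$width, x$height, x$fps, x$n_frames))
  invisible(x)
}

#' Detections observed on one frame
#'
#' @param frame 0-based frame index.
#' @param dets A box table.
#' @return A list of class `frame_detections`.
#' @export
frame_detections <- function(frame, dets = empty_boxes()) {
  structure(list(frame = as.integer(frame), dets = validate_boxes(dets)),
            class = "frame_detections")
}
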