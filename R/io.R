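#' Read and write MOT-style detection CSV files
#'
#' The on-disk dialect is the MOT-Challenge detection format: comma-separated
#' rows `frame,id,x,y,w,h,conf` with no header and 1-based frame indices.
#' Frame indices are converted to 0-based internally. On read the `id`
#' column is ignored for detections and used to group ground-truth
#' trajectories.
#'
#' @param path File path.
#' @return For [read_detections_csv()], a `data.frame` with columns
#'   `frame` (0-based), `id`, `x`, `y`, `w`, `h`, `conf`.
#' @export
read_detections_csv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (file.size(path) == 0L) return(empty_det_df())
  raw <- utils::read.csv(path, header = FALSE, colClasses = "character",
                         strip.white = TRUE)
  if (ncol(raw) < 7)
    stop("malformed detections file: expected 7 columns, got ", ncol(raw),
         call. = FALSE)
  df <- data.frame(frame = suppressWarnings(as.integer(raw[[1]])),
                   id = suppressWarnings(as.integer(raw[[2]])),
                   x = suppressWarnings(as.numeric(raw[[3]])),
                   y = suppressWarnings(as.numeric(raw[[4]])),
                   w = suppressWarnings(as.numeric(raw[[5]])),
                   h = suppressWarnings(as.numeric(raw[[6]])),
                   conf = suppressWarnings(as.numeric(raw[[7]])))
  bad <- which(is.na(df$frame) | is.na(df$x) | is.na(df$y) |
                 is.na(df$w) | is.na(df$h))
  if (length(bad))
    stop("malformed row at line ", bad[1], " of ", path, call. = FALSE)
  if (any(df$w <= 0 | df$h <= 0))
    stop("invalid box (non-positive width/height) at line ",
         which(df$w <= 0 | df$h <= 0)[1], " of ", path, call. = FALSE)
  df$frame <- df$frame - 1L  # 1-based on disk, 0-based in memory
  df[order(df$frame), , drop = FALSE]
}

empty_det_df <- function() {
  data.frame(frame = integer(), id = integer(), x = numeric(), y = numeric(),
             w = numeric(), h = numeric(), conf = numeric())
}

#' @rdname read_detections_csv
#' @param df A `data.frame` with columns `frame` (0-based), `x`, `y`, `w`,
#'   `h` and optionally `id`, `conf`.
#' @export
write_detections_csv <- function(df, path) {
  if (is.null(df$id)) df$id <- -1L
  if (is.null(df$conf)) df$conf <- 1
  df$conf[is.na(df$conf)] <- 1
  out <- data.frame(frame = df$frame + 1L, id = df$id, x = df$x, y = df$y,
                    w = df$w, h = df$h, conf = df$conf)
  utils::write.table(out, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Convert a detection table to a per-frame stream
#'
#' @param df Detection `data.frame` as from [read_detections_csv()].
#' @param n_frames Stream length; frames absent from the table are empty.
#' @return List of box tables, one per frame (element `i` = frame `i - 1`).
#' @export
detections_to_stream <- function(df, n_frames) {
  n_frames <- as.integer(n_frames)
  if (nrow(df) && max(df$frame) >= n_frames)
    stop("detection frame index ", max(df$frame),
         " exceeds stream length ", n_frames, call. = FALSE)
  fr <- factor(df$frame, levels = seq_len(n_frames) - 1L)
  out <- lapply(split(df[, c("x", "y", "w", "h", "conf")], fr),
                validate_boxes)
  names(out) <- NULL
  out
}

#' Ground-truth trajectories from a MOT-style CSV
#'
#' @inheritParams read_detections_csv
#' @return List of per-object trajectory `data.frame`s (columns
#'   `frame`, `x`, `y`, `w`, `h`), one per distinct `id`.
#' @export
read_gt_csv <- function(path) {
  df <- read_detections_csv(path)
  gt_to_trajectories(df)
}

#' @rdname read_gt_csv
#' @param df Detection `data.frame` with an `id` column.
#' @export
gt_to_trajectories <- function(df) {
  if (nrow(df) == 0L) return(list())
  out <- lapply(split(df[, c("frame", "x", "y", "w", "h")], df$id),
                function(d) d[order(d$frame), , drop = FALSE])
  names(out) <- NULL
  out
}

#' Serialize a synthetic scene to MOT-style CSV files
#'
#' @param scene A scene from [generate_scene()].
#' @param dir Output directory (created if needed).
#' @return Paths of the written `gt.csv` and `dets.csv` (invisibly).
#' @export
write_scene_csv <- function(scene, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  gt_rows <- mapply(function(traj, id) cbind(traj, id = id),
                    scene$gt, seq_along(scene$gt), SIMPLIFY = FALSE)
  gt_df <- if (length(gt_rows)) do.call(rbind, gt_rows) else empty_det_df()
  gt_path <- file.path(dir, "gt.csv")
  write_detections_csv(gt_df, gt_path)
  det_rows <- mapply(function(d, i) if (nrow(d)) cbind(frame = i - 1L, d),
                     scene$detections, seq_along(scene$detections),
                     SIMPLIFY = FALSE)
  det_rows <- det_rows[vapply(det_rows, is.data.frame, logical(1))]
  det_df <- if (length(det_rows)) do.call(rbind, det_rows) else empty_det_df()
  det_path <- file.path(dir, "dets.csv")
  write_detections_csv(det_df, det_path)
  invisible(c(gt = gt_path, dets = det_path))
}

#' Parse a compact video-metadata string
#'
#' @param s A string like `"1280x720@60"`.
#' @param n_frames Frame count to attach.
#' @return A [video_meta()].
#' @export
parse_meta_string <- function(s, n_frames = 0L) {
  m <- regmatches(s, regexec("^([0-9]+)x([0-9]+)(@([0-9.]+))?$", s))[[1]]
  if (length(m) == 0L)
    stop("cannot parse video metadata string: ", s, call. = FALSE)
  fps <- if (m[5] == "") 60 else as.numeric(m[5])
  video_meta(as.numeric(m[2]), as.numeric(m[3]), fps, n_frames)
}
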