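#' Run the counting pipeline over a detection stream
#'
#' Replays per-frame detections through the frame scheduler, the SORT
#' tracker and the line counter, with effective-FPS bookkeeping. Skipped
#' frames are never looked at: the scheduler decides from its own state
#' (and, in adaptive mode, from the content of the frames it did process).
#' Per processed frame the order is: confidence filtering, tracker step,
#' count update, then the adaptive rule reacting to whether any detection
#' survived filtering.
#'
#' Counts are deterministic given the inputs and configuration; only the
#' measured FPS values depend on wall-clock timing. Pass `frame_time` to
#' replace timing with a fixed per-frame cost for fully reproducible
#' reports.
#'
#' @param detections Either a list of box tables (one per frame), a
#'   detection `data.frame` as from [read_detections_csv()], or a
#'   `trawl_scene` from [generate_scene()].
#' @param meta A [video_meta()]; taken from the scene when one is given.
#'   If `n_frames` is 0 it is inferred from the detections.
#' @param tracker_cfg A [tracker_config()].
#' @param counter_cfg A [counter_config()].
#' @param skip_mode One of `"none"`, `"fs1"`, `"fs2"`, `"fs3"`,
#'   `"adaptive"`.
#' @param conf_threshold Detection confidence threshold (default 0.5).
#' @param frame_time Optional fixed processing time per frame in seconds;
#'   `NULL` (default) measures wall time.
#' @param seed Optional seed set before the run; the pipeline itself draws
#'   no random numbers, so this only pins downstream consumers.
#' @return A list of class `trawl_report` with the total `count`, the
#'   `events` table, per-frame effective `fps` values and their summary,
#'   schedule tallies (`frames_processed`, `frames_with_detections`,
#'   `frames_skipped`), the `real_time` flag (mean effective FPS at or
#'   above the native rate), and the observation histories of counted
#'   tracks for evaluation.
#' @export
run_pipeline <- function(detections, meta = NULL,
                         tracker_cfg = tracker_config(),
                         counter_cfg = counter_config(),
                         skip_mode = c("none", "fs1", "fs2", "fs3",
                                       "adaptive"),
                         conf_threshold = 0.5, frame_time = NULL,
                         seed = NULL) {
  skip_mode <- match.arg(skip_mode)
  if (!is.null(seed)) set.seed(seed)
  if (inherits(detections, "trawl_scene")) {
    if (is.null(meta)) meta <- detections$meta
    detections <- detections$detections
  }
  if (is.null(meta)) meta <- video_meta()
  if (is.data.frame(detections)) {
    n <- if (meta$n_frames > 0L) meta$n_frames else
      if (nrow(detections)) max(detections$frame) + 1L else 0L
    detections <- detections_to_stream(detections, n)
  }
  n <- length(detections)
  if (meta$n_frames > 0L && meta$n_frames != n)
    stop("meta$n_frames (", meta$n_frames, ") does not match the ",
         "detection stream length (", n, ")", call. = FALSE)
  meta$n_frames <- n

  tracker <- sort_tracker(tracker_cfg)
  cstate <- counter_state()
  fps_vals <- numeric(0)
  frames_processed <- 0L
  frames_with_det <- 0L

  process_frame <- function(i, sb) {
    t0 <- proc.time()[["elapsed"]]
    kept <- filter_by_confidence(detections[[i + 1L]], conf_threshold)
    st <- tracker_step(tracker, kept, i)
    tracker <<- st$tracker
    up <- update_counts(cstate, st$tracks, i, meta, counter_cfg)
    cstate <<- up$state
    dt <- if (is.null(frame_time))
      max(proc.time()[["elapsed"]] - t0, 1e-6) else frame_time
    fps_vals <<- c(fps_vals, effective_fps(dt, sb))
    frames_processed <<- frames_processed + 1L
    present <- nrow(kept) > 0L
    frames_with_det <<- frames_with_det + present
    present
  }

  if (skip_mode == "adaptive") {
    st <- schedule_state("adaptive")
    i <- 0L
    while (i < n) {
      nx <- adaptive_next(st)
      st <- nx$state
      i <- i + nx$n_skip
      if (i >= n) break
      present <- process_frame(i, min(nx$n_skip, i))
      st <- adaptive_after(st, present)
      i <- i + 1L
    }
  } else {
    mask <- fixed_decision(skip_mode, seq_len(n) - 1L)
    sb <- skipped_before(mask)
    idx <- which(mask) - 1L
    for (k in seq_along(idx)) process_frame(idx[k], sb[k])
  }

  events <- cstate$events
  hist <- tracker_histories(tracker)
  hist <- hist[as.character(events$track_id)]
  structure(list(
    meta = meta, skip_mode = skip_mode, conf_threshold = conf_threshold,
    tracker_config = tracker_cfg, counter_config = counter_cfg,
    count = nrow(events), events = events,
    fps = fps_vals,
    fps_summary = if (length(fps_vals)) fps_summary(fps_vals) else NULL,
    frames_processed = frames_processed,
    frames_with_detections = frames_with_det,
    frames_skipped = n - frames_processed,
    real_time = length(fps_vals) > 0 && mean(fps_vals) >= meta$fps,
    track_histories = hist,
    evaluation = NULL
  ), class = "trawl_report")
}

#' @export
print.trawl_report <- function(x, ...) {
  cat(sprintf("trawl counting run (skip mode: %s)\n", x$skip_mode))
  print(x$meta)
  cat(sprintf("catch count: %d\n", x$count))
  cat(sprintf("frames: %d processed (%d with detections), %d skipped\n",
              x$frames_processed, x$frames_with_detections,
              x$frames_skipped))
  if (!is.null(x$fps_summary)) {
    cat("effective ")
    print(x$fps_summary)
    cat(sprintf("real-time (mean >= %g FPS): %s\n", x$meta$fps,
                if (x$real_time) "yes" else "no"))
  }
  if (!is.null(x$evaluation)) {
    cat("evaluation vs ground truth: ")
    print(x$evaluation$tally)
  }
  invisible(x)
}

#' Evaluate a run report against ground truth
#'
#' Matches the counted tracks to ground-truth trajectories
#' ([match_counts_to_gt()]) and attaches the tally, correct count rate and
#' F-score to the report.
#'
#' @param report A `trawl_report` from [run_pipeline()].
#' @param gt Ground truth: a list of trajectories, a `trawl_scene`, or a
#'   path to a MOT-style CSV file.
#' @param spatio_iou_min Matching threshold, see [match_counts_to_gt()].
#' @return The report with an `evaluation` block
#'   (`tally`, `correct_count_rate`, `f_score`).
#' @export
evaluate_report <- function(report, gt, spatio_iou_min = 0.5) {
  if (inherits(gt, "trawl_scene")) gt <- gt$gt
  if (is.character(gt)) gt <- read_gt_csv(gt)
  if (length(gt) == 0L)
    stop("ground truth is empty; counting metrics are undefined",
         call. = FALSE)
  tally <- match_counts_to_gt(report$events, report$track_histories, gt,
                              spatio_iou_min)
  report$evaluation <- list(tally = tally,
                            correct_count_rate = correct_count_rate(tally),
                            f_score = f_score(tally))
  report
}

#' Serialize a run report
#'
#' Writes the full report as JSON (configuration echo, events, FPS values,
#' tallies, and the evaluation block when present) and, separately, the
#' count events as CSV.
#'
#' @param report A `trawl_report`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  out <- unclass(report)
  out$meta <- unclass(out$meta)
  out$tracker_config <- unclass(out$tracker_config)
  out$counter_config <- unclass(out$counter_config)
  if (!is.null(out$fps_summary)) out$fps_summary <- unclass(out$fps_summary)
  if (!is.null(out$evaluation)) {
    out$evaluation$tally <- unclass(out$evaluation$tally)
    out$evaluation$correct_count_rate <-
      round(out$evaluation$correct_count_rate, 2)
    out$evaluation$f_score <- round(out$evaluation$f_score, 2)
  }
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_report_json
#' @export
read_report_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$track_histories <- lapply(x$track_histories, as.data.frame)
  x$events <- as.data.frame(x$events)
  class(x) <- "trawl_report"
  x
}

#' @rdname write_report_json
#' @export
write_events_csv <- function(report, path) {
  utils::write.csv(report$events, path, row.names = FALSE)
  invisible(path)
}
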