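#' Frame-skipping schedules
#'
#' Which frames of the native stream are processed. Five modes:
#'
#' * `none` — every frame is processed.
#' * `fs1` — skip every third frame (period 3; process, process, skip).
#' * `fs2` — skip every second frame (period 2; process, skip).
#' * `fs3` — skip every second and third frames (period 3; process, skip,
#'   skip).
#' * `adaptive` — content-driven: after a processed frame with no target
#'   detections, skip the next two frames and process the third; after a
#'   processed frame with detections, process the next two frames. The same
#'   rule is re-checked at every processed frame until the end of the video.
#'
#' Frame 0 is always processed in every mode.
#'
#' @name schedules
NULL

SKIP_MODES <- c("none", "fs1", "fs2", "fs3", "adaptive")

#' Fixed-pattern process/skip decision
#'
#' @param mode One of `"none"`, `"fs1"`, `"fs2"`, `"fs3"`.
#' @param frame_index 0-based frame index (vectorized).
#' @return Logical: `TRUE` where the frame is processed.
#' @export
fixed_decision <- function(mode, frame_index) {
  mode <- match.arg(mode, SKIP_MODES)
  if (mode == "adaptive")
    stop("fixed_decision() does not apply to the adaptive mode", call. = FALSE)
  i <- as.integer(frame_index)
  switch(mode,
         none = rep(TRUE, length(i)),
         fs1 = i %% 3L != 2L,
         fs2 = i %% 2L == 0L,
         fs3 = i %% 3L == 0L)
}

#' Scheduler state
#'
#' For the adaptive mode, `forced_remaining` counts upcoming frames already
#' committed to processing; it starts at 1 so that frame 0 is processed, and
#' is raised to 2 whenever a processed frame contains detections.
#'
#' @param mode One of the five skip modes.
#' @return A list of class `schedule_state`.
#' @export
schedule_state <- function(mode = "none") {
  mode <- match.arg(mode, SKIP_MODES)
  structure(list(mode = mode,
                 forced_remaining = if (mode == "adaptive") 1L else 0L,
                 frames_processed = 0L, frames_skipped = 0L,
                 skipped_before_current = 0L),
            class = "schedule_state")
}

#' Adaptive rule: react to the content of a processed frame
#'
#' Called exactly once per processed frame, after detection. If targets were
#' present, the next two frames are committed to processing (max-merged with
#' any outstanding commitment); otherwise the state is unchanged and the
#' idle pattern (skip two, process the third) applies.
#'
#' @param state A [schedule_state()] in adaptive mode.
#' @param detections_present Logical: any detection on the processed frame.
#' @return Updated state.
#' @export
adaptive_after <- function(state, detections_present) {
  stopifnot(state$mode == "adaptive")
  if (isTRUE(detections_present))
    state$forced_remaining <- max(state$forced_remaining, 2L)
  state
}

#' Adaptive rule: emit the next schedule block
#'
#' Decides how many frames to skip before the next processed frame: none
#' while commitments remain, otherwise two. Updates the processed/skipped
#' tallies and `skipped_before_current`.
#'
#' @param state A [schedule_state()] in adaptive mode.
#' @return A list with the updated `state` and `n_skip`, the number of
#'   frames skipped before the next processed frame.
#' @export
adaptive_next <- function(state) {
  stopifnot(state$mode == "adaptive")
  if (state$forced_remaining > 0L) {
    n_skip <- 0L
    state$forced_remaining <- state$forced_remaining - 1L
  } else {
    n_skip <- 2L
  }
  state$skipped_before_current <- n_skip
  state$frames_skipped <- state$frames_skipped + n_skip
  state$frames_processed <- state$frames_processed + 1L
  list(state = state, n_skip = n_skip)
}

#' Processed-frame mask for a whole stream
#'
#' For fixed modes this is the periodic pattern; for the adaptive mode the
#' per-frame presence of detections must be supplied (it is consulted only
#' at processed frames, as in a real run).
#'
#' @param mode One of the five skip modes.
#' @param n_frames Number of frames in the stream.
#' @param presence Logical vector of length `n_frames`: whether detections
#'   are present on each frame (adaptive mode only).
#' @return Logical vector: `TRUE` where the frame is processed.
#' @export
schedule_mask <- function(mode, n_frames, presence = NULL) {
  mode <- match.arg(mode, SKIP_MODES)
  n_frames <- as.integer(n_frames)
  if (mode != "adaptive")
    return(fixed_decision(mode, seq_len(n_frames) - 1L))
  stopifnot(is.logical(presence), length(presence) == n_frames)
  mask <- logical(n_frames)
  st <- schedule_state("adaptive")
  i <- 1L
  while (i <= n_frames) {
    nx <- adaptive_next(st)
    st <- nx$state
    i <- i + nx$n_skip
    if (i > n_frames) break
    mask[i] <- TRUE
    st <- adaptive_after(st, presence[i])
    i <- i + 1L
  }
  mask
}

#' Frames skipped immediately before each processed frame
#'
#' @param mask Logical processed-frame mask.
#' @return Integer vector, one entry per processed frame.
#' @export
skipped_before <- function(mask) {
  idx <- which(mask)
  if (length(idx) == 0L) return(integer(0))
  diff(c(0L, idx)) - 1L
}

#' Effective frames-per-second of a processed frame
#'
#' The reciprocal of the frame's processing time, multiplied by one more
#' than the number of frames skipped immediately before it — a skipped frame
#' costs nothing, so each processed frame accounts for itself plus the
#' frames skipped just before it. For example, 50 ms under the `fs2`
#' schedule (one skipped frame before each processed one) gives
#' 2 x 20 = 40 FPS.
#'
#' @param frame_time Processing time of the frame in seconds; must be > 0.
#' @param skipped_before Number of frames skipped immediately before the
#'   frame.
#' @return Effective FPS (vectorized).
#' @export
effective_fps <- function(frame_time, skipped_before = 0) {
  if (any(frame_time <= 0))
    stop("frame_time must be positive", call. = FALSE)
  (1 + skipped_before) / frame_time
}
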