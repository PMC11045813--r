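#' Counting-line configuration
#'
#' A virtual horizontal level is placed at `line_fraction` of the frame
#' height, measured downward from the top edge (default 4/5, i.e. near the
#' bottom of the frame where catch items leave toward the codend). A
#' confirmed track is counted as a catch the first time any enabled
#' condition holds:
#'
#' * `bottom_cross` — the bottom of the bounding box crosses the level,
#' * `center_cross` — the center of the bounding box crosses the level,
#' * `tall_box` — the box height exceeds `height_fraction` of the frame
#'   height (strict `>`; default 2/3), which catches individuals so close to
#'   the camera that they fill the frame without a visible crossing.
#'
#' "Crosses" means an observed above-to-below transition between two
#' consecutive processed observations of the track (y grows downward);
#' the boundary is inclusive on the below side.
#'
#' @param line_fraction Position of the counting line as a fraction of frame
#'   height, in (0, 1).
#' @param height_fraction Box-height threshold for `tall_box`, in (0, 1\].
#' @param enabled_conditions Non-empty subset of
#'   `c("bottom_cross", "center_cross", "tall_box")`.
#' @param count_on_first_sight_below Count a track whose very first
#'   observation is already past the line (no transition was observed).
#'   Default `FALSE`: only witnessed crossings count.
#' @param count_on_predicted Evaluate conditions on Kalman-predicted boxes of
#'   coasting tracks as well. Default `FALSE`: only observed detections
#'   count, which avoids counting coasting ghosts.
#' @return A list of class `counter_config`.
#' @export
counter_config <- function(line_fraction = 4 / 5, height_fraction = 2 / 3,
                           enabled_conditions = c("bottom_cross",
                                                  "center_cross", "tall_box"),
                           count_on_first_sight_below = FALSE,
                           count_on_predicted = FALSE) {
  stopifnot(line_fraction > 0, line_fraction < 1,
            height_fraction > 0, height_fraction <= 1,
            length(enabled_conditions) > 0,
            all(enabled_conditions %in%
                  c("bottom_cross", "center_cross", "tall_box")))
  structure(list(line_fraction = line_fraction,
                 height_fraction = height_fraction,
                 enabled_conditions = enabled_conditions,
                 count_on_first_sight_below =
                   isTRUE(count_on_first_sight_below),
                 count_on_predicted = isTRUE(count_on_predicted)),
            class = "counter_config")
}

#' Pixel position of the counting line
#'
#' @param meta A [video_meta()].
#' @param cfg A [counter_config()].
#' @return y position of the line in pixels from the top edge
#'   (576 for the default 4/5 line in a 720-px frame).
#' @export
line_y <- function(meta, cfg = counter_config()) {
  cfg$line_fraction * meta$height
}

#' Count conditions
#'
#' The three per-track predicates; see [counter_config()] for their meaning.
#'
#' @param prev,cur One-row box tables at the track's two most recent
#'   processed observations.
#' @param line Counting-line position in pixels.
#' @return Logical.
#' @export
condition_bottom_cross <- function(prev, cur, line) {
  box_bottom(prev) < line && box_bottom(cur) >= line
}

#' @rdname condition_bottom_cross
#' @export
condition_center_cross <- function(prev, cur, line) {
  box_center_y(prev) < line && box_center_y(cur) >= line
}

#' @rdname condition_bottom_cross
#' @param meta A [video_meta()].
#' @param cfg A [counter_config()].
#' @export
condition_tall_box <- function(cur, meta, cfg = counter_config()) {
  cur$h > cfg$height_fraction * meta$height
}

#' Create an empty counter state
#'
#' @return A list of class `counter_state` holding the count events emitted
#'   so far, each track's last observed box, and the set of already-counted
#'   track ids.
#' @export
counter_state <- function() {
  structure(list(events = empty_events(), last_box = list(),
                 counted = character(0)),
            class = "counter_state")
}

empty_events <- function() {
  data.frame(track_id = integer(), frame = integer(),
             condition = character())
}

#' Update catch counts with one processed frame of confirmed tracks
#'
#' Evaluates the enabled conditions for every track and emits a count event
#' the first time any condition holds; a track already counted is never
#' re-counted, so the cumulative count is the number of events. Conditions
#' are checked in the fixed order bottom_cross, center_cross, tall_box and
#' the first that fires is recorded.
#'
#' @param state A [counter_state()].
#' @param tracks The `tracks` data.frame returned by [tracker_step()].
#' @param frame 0-based frame index of this processed frame.
#' @param meta A [video_meta()].
#' @param cfg A [counter_config()].
#' @return A list with the updated `state` and `new_events`, the events
#'   emitted on this frame.
#' @export
update_counts <- function(state, tracks, frame, meta,
                          cfg = counter_config()) {
  stopifnot(inherits(state, "counter_state"))
  frame <- as.integer(frame)
  line <- line_y(meta, cfg)
  tall_h <- cfg$height_fraction * meta$height
  conds <- intersect(c("bottom_cross", "center_cross", "tall_box"),
                     cfg$enabled_conditions)
  new_events <- empty_events()
  use <- if (cfg$count_on_predicted) seq_len(nrow(tracks)) else
    which(tracks$observed)
  ids <- tracks$track_id; tx <- tracks$x; ty <- tracks$y
  tw <- tracks$w; th <- tracks$h
  for (k in use) {
    key <- as.character(ids[k])
    cur <- list(x = tx[k], y = ty[k], w = tw[k], h = th[k])
    prev <- state$last_box[[key]]
    state$last_box[[key]] <- cur
    if (key %in% state$counted) next
    fired <- NA_character_
    for (cond in conds) {
      hit <- switch(cond,
        bottom_cross = if (!is.null(prev))
          prev$y + prev$h < line && cur$y + cur$h >= line
          else cfg$count_on_first_sight_below && cur$y + cur$h >= line,
        center_cross = !is.null(prev) &&
          prev$y + prev$h / 2 < line && cur$y + cur$h / 2 >= line,
        tall_box = cur$h > tall_h)
      if (isTRUE(hit)) { fired <- cond; break }
    }
    if (!is.na(fired)) {
      state$counted <- c(state$counted, key)
      new_events <- rbind(new_events,
                          data.frame(track_id = ids[k], frame = frame,
                                     condition = fired))
    }
  }
  state$events <- rbind(state$events, new_events)
  list(state = state, new_events = new_events)
}
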