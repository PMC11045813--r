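#' Tracker configuration
#'
#' Parameters of the SORT-style tracker: a constant-velocity Kalman filter
#' over the box state `(u, v, s, r, du, dv, ds)` — box center `(u, v)`,
#' area `s`, aspect ratio `r = w/h` (held constant), and per-step velocities
#' of the first three — with IoU-optimal one-to-one assignment of detections
#' to predicted tracks.
#'
#' The noise matrices follow the reference SORT formulation; none of these
#' values are dictated by the counting rules, and all are exposed here.
#'
#' @param iou_min Minimum IoU for a detection-track match, in (0, 1).
#' @param max_age Frames a track may coast without an update before deletion.
#' @param min_hits Updates required before a track is confirmed (reported).
#' @param predict_through_skips If `TRUE`, the Kalman filter is advanced once
#'   per elapsed native frame, so skipped frames still age the motion model;
#'   if `FALSE` (default) the tracker's clock ticks once per processed frame.
#' @param p0_diag,q_diag,r_diag Diagonals of the initial state covariance,
#'   process noise and measurement noise (state order `u,v,s,r,du,dv,ds`;
#'   measurement order `u,v,s,r`).
#' @return A list of class `tracker_config`.
#' @export
tracker_config <- function(iou_min = 0.3, max_age = 3L, min_hits = 3L,
                           predict_through_skips = FALSE,
                           p0_diag = c(10, 10, 10, 10, 1e4, 1e4, 1e4),
                           q_diag = c(1, 1, 1, 1, 0.01, 0.01, 1e-4),
                           r_diag = c(1, 1, 10, 10)) {
  stopifnot(iou_min > 0, iou_min < 1, max_age >= 1, min_hits >= 1,
            length(p0_diag) == 7, length(q_diag) == 7, length(r_diag) == 4)
  structure(list(iou_min = iou_min, max_age = as.integer(max_age),
                 min_hits = as.integer(min_hits),
                 predict_through_skips = isTRUE(predict_through_skips),
                 p0_diag = p0_diag, q_diag = q_diag, r_diag = r_diag),
            class = "tracker_config")
}

# --- box <-> measurement conversions (internal: plain numeric vectors) ----

box_to_z <- function(x, y, w, h) {
  c(x + w / 2, y + h / 2, w * h, w / h)
}

z_to_box_vec <- function(z) {
  w <- sqrt(z[3] * z[4])
  c(z[1] - w / 2, z[2] - z[3] / w / 2, w, z[3] / w)
}

# --- Kalman filter --------------------------------------------------------

kf_matrices <- function(cfg) {
  f <- diag(7)
  f[1, 5] <- f[2, 6] <- f[3, 7] <- 1
  h <- matrix(0, 4, 7)
  h[1, 1] <- h[2, 2] <- h[3, 3] <- h[4, 4] <- 1
  list(F = f, H = h, Q = diag(cfg$q_diag), R = diag(cfg$r_diag))
}

kf_init <- function(z, cfg) {
  list(x = c(z, 0, 0, 0), P = diag(cfg$p0_diag))
}

kf_predict <- function(kf, mats) {
  # keep the predicted area >= 1 px^2 so the state stays convertible to a box
  if (kf$x[3] + kf$x[7] < 1) kf$x[7] <- 1 - kf$x[3]
  kf$x <- drop(mats$F %*% kf$x)
  kf$P <- mats$F %*% kf$P %*% t(mats$F) + mats$Q
  kf
}

kf_update <- function(kf, z, mats) {
  y <- z - kf$x[1:4]
  s <- kf$P[1:4, 1:4] + mats$R
  k <- kf$P[, 1:4] %*% solve(s)
  kf$x <- kf$x + drop(k %*% y)
  kf$P <- kf$P - k %*% kf$P[1:4, , drop = FALSE]
  kf
}

# --- track lifecycle ------------------------------------------------------

#' Start a new track from an unmatched detection
#'
#' The new track's velocities are zero, it has one hit, and its history
#' holds the initiating detection.
#'
#' @param det A one-row box table.
#' @param id Unique integer track id.
#' @param cfg A [tracker_config()].
#' @param frame 0-based frame index of the detection.
#' @return A track record (internal list).
#' @export
init_track <- function(det, id, cfg = tracker_config(), frame = 0L) {
  det <- validate_boxes(det)
  stopifnot(nrow(det) == 1L)
  new_track(det$x, det$y, det$w, det$h, det$conf, id, cfg, as.integer(frame))
}

new_track <- function(x, y, w, h, conf, id, cfg, frame) {
  tr <- list(id = as.integer(id),
             kf = kf_init(box_to_z(x, y, w, h), cfg),
             hits = 1L, time_since_update = 0L, confirmed = FALSE,
             history = list(list(frame = frame, box = c(x, y, w, h, conf))))
  if (tr$hits >= cfg$min_hits) tr$confirmed <- TRUE
  tr
}

#' Advance a track one step and return its predicted box
#'
#' Applies the constant-velocity transition and increments the track's
#' `time_since_update` counter.
#'
#' @param track A track record from [init_track()].
#' @param cfg A [tracker_config()].
#' @return A list with the advanced `track` and the predicted `box` (a
#'   one-row box table).
#' @export
predict_track <- function(track, cfg = tracker_config()) {
  mats <- kf_matrices(cfg)
  track$kf <- kf_predict(track$kf, mats)
  track$time_since_update <- track$time_since_update + 1L
  b <- z_to_box_vec(track$kf$x[1:4])
  list(track = track, box = boxes(b[1], b[2], b[3], b[4]))
}

# --- association ----------------------------------------------------------

#' Associate detections to predicted tracks
#'
#' One-to-one matching that maximizes total IoU, with pairs below `iou_min`
#' disallowed. The three outputs partition the inputs.
#'
#' @param iou_mat Matrix of IoU values, tracks in rows, detections in columns.
#' @param iou_min Minimum IoU for a valid match.
#' @return A list with `matches` (two-column integer matrix: track row index,
#'   detection column index), `unmatched_tracks` and `unmatched_dets`
#'   (integer index vectors).
#' @export
associate <- function(iou_mat, iou_min = 0.3) {
  nt <- nrow(iou_mat); nd <- ncol(iou_mat)
  if (nt == 0L || nd == 0L) {
    return(list(matches = matrix(integer(0), 0, 2),
                unmatched_tracks = seq_len(nt),
                unmatched_dets = seq_len(nd)))
  }
  score <- ifelse(iou_mat >= iou_min, iou_mat, 0)
  pairs <- max_score_assignment(score)
  ok <- iou_mat[pairs] >= iou_min
  matches <- pairs[ok, , drop = FALSE]
  list(matches = matches,
       unmatched_tracks = setdiff(seq_len(nt), matches[, 1]),
       unmatched_dets = setdiff(seq_len(nd), matches[, 2]))
}

# IoU matrix from coordinate vectors, avoiding data.frame overhead in the
# per-frame loop.
iou_matrix_vec <- function(ax, ay, aw, ah, bx, by, bw, bh) {
  na <- length(ax); nb <- length(bx)
  m <- matrix(0, na, nb)
  if (na == 0L || nb == 0L) return(m)
  area_a <- aw * ah
  for (j in seq_len(nb)) {
    ix <- pmax(0, pmin(ax + aw, bx[j] + bw[j]) - pmax(ax, bx[j]))
    iy <- pmax(0, pmin(ay + ah, by[j] + bh[j]) - pmax(ay, by[j]))
    inter <- ix * iy
    m[, j] <- inter / (area_a + bw[j] * bh[j] - inter)
  }
  m
}

# --- tracker --------------------------------------------------------------

#' Create a SORT tracker
#'
#' The tracker is a value: [tracker_step()] returns an updated copy, so runs
#' are reproducible and trivially testable.
#'
#' @param cfg A [tracker_config()].
#' @return A list of class `sort_tracker`.
#' @export
sort_tracker <- function(cfg = tracker_config()) {
  structure(list(cfg = cfg, tracks = list(), next_id = 1L,
                 last_frame = -1L, archive = list()),
            class = "sort_tracker")
}

#' Step the tracker with one processed frame of detections
#'
#' Predict all tracks, associate detections by IoU, Kalman-update the matched
#' tracks, start tracks for unmatched detections, delete tracks that have
#' coasted longer than `max_age`, and return the confirmed tracks.
#'
#' @param tracker A [sort_tracker()].
#' @param dets Box table of detections on this frame (already
#'   confidence-filtered).
#' @param frame 0-based frame index; must strictly increase across calls.
#' @return A list with the updated `tracker` and `tracks`, a `data.frame`
#'   of confirmed tracks with columns `track_id`, `x`, `y`, `w`, `h`,
#'   `conf`, `observed` (whether the box is this frame's associated
#'   detection rather than a Kalman prediction), `hits`,
#'   `time_since_update`.
#' @export
tracker_step <- function(tracker, dets, frame) {
  stopifnot(inherits(tracker, "sort_tracker"))
  frame <- as.integer(frame)
  if (frame <= tracker$last_frame)
    stop("frames must be supplied in increasing frame_index order",
         call. = FALSE)
  cfg <- tracker$cfg
  mats <- kf_matrices(cfg)
  dets <- validate_boxes(dets)
  dx <- dets$x; dy <- dets$y; dw <- dets$w; dh <- dets$h; dconf <- dets$conf

  extra <- if (cfg$predict_through_skips && tracker$last_frame >= 0L)
    frame - tracker$last_frame - 1L else 0L

  # predict
  nt <- length(tracker$tracks)
  px <- py <- pw <- ph <- numeric(nt)
  for (i in seq_len(nt)) {
    tr <- tracker$tracks[[i]]
    for (k in seq_len(extra)) tr$kf <- kf_predict(tr$kf, mats)
    tr$kf <- kf_predict(tr$kf, mats)
    tr$time_since_update <- tr$time_since_update + 1L
    tracker$tracks[[i]] <- tr
    b <- z_to_box_vec(tr$kf$x[1:4])
    px[i] <- b[1]; py[i] <- b[2]; pw[i] <- b[3]; ph[i] <- b[4]
  }

  # associate and update
  assoc <- associate(iou_matrix_vec(px, py, pw, ph, dx, dy, dw, dh),
                     cfg$iou_min)
  if (nrow(assoc$matches) > 0L) {
    for (k in seq_len(nrow(assoc$matches))) {
      i <- assoc$matches[k, 1]; j <- assoc$matches[k, 2]
      tr <- tracker$tracks[[i]]
      tr$kf <- kf_update(tr$kf, box_to_z(dx[j], dy[j], dw[j], dh[j]), mats)
      tr$hits <- tr$hits + 1L
      tr$time_since_update <- 0L
      if (tr$hits >= cfg$min_hits) tr$confirmed <- TRUE
      tr$history[[length(tr$history) + 1L]] <-
        list(frame = frame, box = c(dx[j], dy[j], dw[j], dh[j], dconf[j]))
      tracker$tracks[[i]] <- tr
    }
  }

  # births
  for (j in assoc$unmatched_dets) {
    tr <- new_track(dx[j], dy[j], dw[j], dh[j], dconf[j],
                    tracker$next_id, cfg, frame)
    tracker$next_id <- tracker$next_id + 1L
    tracker$tracks[[length(tracker$tracks) + 1L]] <- tr
  }

  # deaths: archive the history so counted tracks stay evaluable
  keep <- vapply(tracker$tracks,
                 function(t) t$time_since_update <= cfg$max_age, logical(1))
  for (tr in tracker$tracks[!keep])
    tracker$archive[[as.character(tr$id)]] <- tr$history
  tracker$tracks <- tracker$tracks[keep]
  tracker$last_frame <- frame

  # output: confirmed tracks with their current boxes
  conf_tr <- Filter(function(t) t$confirmed, tracker$tracks)
  no <- length(conf_tr)
  track_id <- hits <- tsu <- integer(no)
  ox <- oy <- ow <- oh <- oconf <- numeric(no)
  observed <- logical(no)
  for (i in seq_len(no)) {
    tr <- conf_tr[[i]]
    track_id[i] <- tr$id; hits[i] <- tr$hits
    tsu[i] <- tr$time_since_update
    observed[i] <- tr$time_since_update == 0L
    b <- if (observed[i]) tr$history[[length(tr$history)]]$box
    else c(z_to_box_vec(tr$kf$x[1:4]), NA_real_)
    ox[i] <- b[1]; oy[i] <- b[2]; ow[i] <- b[3]; oh[i] <- b[4]
    oconf[i] <- b[5]
  }
  tracks <- data.frame(track_id = track_id, x = ox, y = oy, w = ow, h = oh,
                       conf = oconf, observed = observed, hits = hits,
                       time_since_update = tsu)
  list(tracker = tracker, tracks = tracks)
}

#' Observation histories of all tracks seen in a run
#'
#' @param tracker A stepped [sort_tracker()].
#' @return Named list (by track id) of `data.frame`s with columns
#'   `frame`, `x`, `y`, `w`, `h`.
#' @export
tracker_histories <- function(tracker) {
  all <- tracker$archive
  for (tr in tracker$tracks) all[[as.character(tr$id)]] <- tr$history
  lapply(all, function(hist) {
    m <- do.call(rbind, lapply(hist, function(e) c(e$frame, e$box[1:4])))
    data.frame(frame = as.integer(m[, 1]), x = m[, 2], y = m[, 3],
               w = m[, 4], h = m[, 5])
  })
}
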