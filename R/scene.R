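#' Synthetic in-trawl scene configuration
#'
#' Describes a simulated stream of catch items flowing downward through the
#' camera view toward the codend, together with a noisy detector observing
#' them. Defaults emulate the footage regime this package targets: a
#' 1280 x 720, 60 FPS camera, sparse arrivals (~0.06-0.08 objects per
#' second), boxes of roughly 150 x 110 px that grow slightly as the item
#' approaches, and a detector with occasional dropouts, a couple of pixels
#' of localization noise, and rare spurious boxes.
#'
#' @param meta A [video_meta()]; `n_frames` is derived from `duration`.
#' @param duration Scene length in seconds.
#' @param arrival_rate Expected arrivals in objects/second (Poisson).
#' @param n_objects If given, exactly this many objects are injected at
#'   seeded-random times early enough to traverse the frame; overrides
#'   `arrival_rate`.
#' @param speed_mean,speed_sd Per-object downward speed in pixels/frame.
#' @param speed_jitter_sd Per-frame Gaussian perturbation of the speed
#'   (clamped so trajectories never move upward).
#' @param width_mean,width_sd,height_mean,height_sd Initial box size in
#'   pixels.
#' @param size_growth Fractional box growth per frame as the object
#'   approaches the camera.
#' @param miss_prob Per-frame probability that a visible object is not
#'   detected.
#' @param fp_rate Expected spurious detections per frame (Poisson).
#' @param loc_noise_sd Gaussian localization noise on box corner and size,
#'   in pixels.
#' @param conf_mean,conf_sd Detector confidence model for true detections;
#'   values are clamped to \[0.5, 1\] — the generator emulates a detector
#'   whose reported detections clear the working confidence threshold, and
#'   models sub-threshold failures through `miss_prob` instead.
#' @param seed Integer seed; scenes are fully deterministic given the seed.
#' @return A list of class `scene_config`.
#' @export
scene_config <- function(meta = video_meta(1280, 720, 60),
                         duration = 55, arrival_rate = 0.0727,
                         n_objects = NULL,
                         speed_mean = 6, speed_sd = 1, speed_jitter_sd = 0.5,
                         width_mean = 150, width_sd = 20,
                         height_mean = 110, height_sd = 15,
                         size_growth = 0.001,
                         miss_prob = 0.1, fp_rate = 0.01, loc_noise_sd = 2,
                         conf_mean = 0.85, conf_sd = 0.05, seed = 1L) {
  stopifnot(duration > 0, arrival_rate >= 0,
            miss_prob >= 0, miss_prob <= 1, fp_rate >= 0, loc_noise_sd >= 0)
  structure(list(meta = meta, duration = duration,
                 arrival_rate = arrival_rate, n_objects = n_objects,
                 speed_mean = speed_mean, speed_sd = speed_sd,
                 speed_jitter_sd = speed_jitter_sd,
                 width_mean = width_mean, width_sd = width_sd,
                 height_mean = height_mean, height_sd = height_sd,
                 size_growth = size_growth, miss_prob = miss_prob,
                 fp_rate = fp_rate, loc_noise_sd = loc_noise_sd,
                 conf_mean = conf_mean, conf_sd = conf_sd,
                 seed = as.integer(seed)),
            class = "scene_config")
}

#' Expected number of objects in a scene
#'
#' @param cfg A [scene_config()].
#' @return `arrival_rate * duration`, or `n_objects` when fixed.
#' @export
expected_count <- function(cfg) {
  if (!is.null(cfg$n_objects)) return(cfg$n_objects)
  cfg$arrival_rate * cfg$duration
}

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  code
}

#' Generate a synthetic scene
#'
#' Produces ground-truth trajectories and noisy per-frame detections.
#' Objects arrive as a Poisson process (or at `n_objects` seeded times),
#' enter just above the top edge, move downward with per-frame
#' Gaussian-perturbed speed (clamped non-negative, so trajectories are
#' monotone in y), grow by `size_growth` per frame, and exit at the bottom.
#' Detections are the ground-truth boxes with Gaussian localization noise,
#' dropped with probability `miss_prob`, plus Poisson spurious boxes.
#'
#' The ground-truth catch count is the number of objects whose box bottom
#' reaches the counting line (4/5 of frame height) within the video.
#'
#' @param cfg A [scene_config()].
#' @param detections If `FALSE`, skip building the per-frame detection
#'   stream (trajectories and counts only); useful for large calibration
#'   runs.
#' @return A list of class `trawl_scene` with `meta`, `gt` (list of
#'   per-object trajectory `data.frame`s with columns `frame,x,y,w,h`),
#'   `detections` (list of box tables, one per frame), `gt_count`, and the
#'   `config`.
#' @export
generate_scene <- function(cfg = scene_config(), detections = TRUE) {
  stopifnot(inherits(cfg, "scene_config"))
  with_seed(cfg$seed, {
    meta <- cfg$meta
    fps <- meta$fps
    n_frames <- as.integer(round(cfg$duration * fps))
    meta$n_frames <- n_frames
    H <- meta$height; W <- meta$width
    line <- 4 / 5 * H

    # arrivals
    if (!is.null(cfg$n_objects)) {
      travel <- ceiling((H + 2 * cfg$height_mean) / max(cfg$speed_mean, 1))
      last <- max(0L, n_frames - travel - 1L)
      arrivals <- sort(sample.int(last + 1L, cfg$n_objects,
                                  replace = TRUE) - 1L)
    } else {
      per_frame <- stats::rpois(n_frames, cfg$arrival_rate / fps)
      arrivals <- rep(seq_len(n_frames) - 1L, per_frame)
    }

    gt <- list()
    crossed <- 0L
    for (a in arrivals) {
      w0 <- max(20, stats::rnorm(1, cfg$width_mean, cfg$width_sd))
      h0 <- max(20, stats::rnorm(1, cfg$height_mean, cfg$height_sd))
      cx <- stats::runif(1, 0.15, 0.85) * W
      speed <- max(1, stats::rnorm(1, cfg$speed_mean, cfg$speed_sd))
      # generous horizon, truncated at frame exit below
      t_max <- ceiling((H + 2 * h0) / max(speed - 3 * cfg$speed_jitter_sd, 1)) + 10L
      dy <- pmax(0, stats::rnorm(t_max, speed, cfg$speed_jitter_sd))
      y_top <- -h0 + c(0, cumsum(dy))
      t_rel <- seq_along(y_top) - 1L
      scale <- (1 + cfg$size_growth)^t_rel
      w <- w0 * scale
      h <- h0 * scale
      frame <- a + t_rel
      visible <- y_top + h > 0 & y_top < H & frame < n_frames
      # stop at first exit
      gone <- which(y_top >= H)
      if (length(gone)) visible[gone[1]:length(visible)] <- FALSE
      if (!any(visible)) next
      traj <- data.frame(frame = frame[visible],
                         x = cx - w[visible] / 2, y = y_top[visible],
                         w = w[visible], h = h[visible])
      if (max(traj$y + traj$h) >= line) crossed <- crossed + 1L
      gt[[length(gt) + 1L]] <- traj
    }

    dets <- NULL
    if (detections) {
      all_gt <- if (length(gt)) do.call(rbind, gt) else
        data.frame(frame = integer(), x = numeric(), y = numeric(),
                   w = numeric(), h = numeric())
      n <- nrow(all_gt)
      keep <- stats::runif(n) >= cfg$miss_prob
      obs <- all_gt[keep, , drop = FALSE]
      m <- nrow(obs)
      obs$x <- obs$x + stats::rnorm(m, 0, cfg$loc_noise_sd)
      obs$y <- obs$y + stats::rnorm(m, 0, cfg$loc_noise_sd)
      obs$w <- pmax(4, obs$w + stats::rnorm(m, 0, cfg$loc_noise_sd))
      obs$h <- pmax(4, obs$h + stats::rnorm(m, 0, cfg$loc_noise_sd))
      obs$conf <- pmin(1, pmax(0.5, stats::rnorm(m, cfg$conf_mean,
                                                 cfg$conf_sd)))
      n_sp <- stats::rpois(n_frames, cfg$fp_rate)
      k <- sum(n_sp)
      if (k > 0L) {
        sp <- data.frame(frame = rep(seq_len(n_frames) - 1L, n_sp),
                         w = stats::runif(k, 30, 120),
                         h = stats::runif(k, 30, 120))
        sp$x <- stats::runif(k, 0, W - sp$w)
        sp$y <- stats::runif(k, 0, H - sp$h)
        sp$conf <- stats::runif(k, 0.5, 0.9)
        obs <- rbind(obs, sp[, names(obs)])
      }
      fr <- factor(obs$frame, levels = seq_len(n_frames) - 1L)
      dets <- lapply(split(obs[, c("x", "y", "w", "h", "conf")], fr),
                     function(d) validate_boxes(d))
      names(dets) <- NULL
    }

    structure(list(meta = meta, gt = gt, detections = dets,
                   gt_count = crossed, config = cfg),
              class = "trawl_scene")
  })
}

#' @export
print.trawl_scene <- function(x, ...) {
  cat(sprintf("synthetic scene: %d frames, %d objects (%d crossing the line)\n",
              x$meta$n_frames, length(x$gt), x$gt_count))
  invisible(x)
}
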