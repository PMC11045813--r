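#' Counting tally
#'
#' Bookkeeping of counted tracks against ground truth: each counted track is
#' a true positive (TP) if it corresponds to a real catch item, otherwise a
#' false positive (FP); ground-truth items never counted are false negatives
#' (FN). `TP + FN = GT` when the tally comes from matching.
#'
#' @param tp,fp,fn,gt Non-negative counts.
#' @return A list of class `counting_tally`.
#' @export
counting_tally <- function(tp, fp, fn, gt) {
  stopifnot(tp >= 0, fp >= 0, fn >= 0, gt >= 0, tp <= gt)
  structure(list(tp = as.integer(tp), fp = as.integer(fp),
                 fn = as.integer(fn), gt = as.integer(gt)),
            class = "counting_tally")
}

#' @export
print.counting_tally <- function(x, ...) {
  cat(sprintf("TP %d  FP %d  FN %d  GT %d\n", x$tp, x$fp, x$fn, x$gt))
  if (x$gt > 0)
    cat(sprintf("correct count rate %.2f%%  F-score %.2f\n",
                correct_count_rate(x), f_score(x)))
  invisible(x)
}

#' Correct count rate
#'
#' Percentage of ground-truth catch items correctly counted:
#' `100 * TP / GT`.
#'
#' @param t A [counting_tally()] with `gt > 0`.
#' @return Percentage in \[0, 100\].
#' @export
correct_count_rate <- function(t) {
  if (t$gt == 0L)
    stop("correct count rate is undefined for GT = 0", call. = FALSE)
  100 * t$tp / t$gt
}

#' Counting F-score
#'
#' `TP / (TP + 0.5 * (FP + FN))` — the harmonic-mean style accuracy that
#' weighs false and missed counts together.
#'
#' @param t A [counting_tally()] with at least one nonzero field.
#' @return Ratio in \[0, 1\].
#' @export
f_score <- function(t) {
  denom <- t$tp + 0.5 * (t$fp + t$fn)
  if (denom == 0)
    stop("F-score is undefined for an all-zero tally", call. = FALSE)
  t$tp / denom
}

#' Summarize per-frame effective FPS values
#'
#' @param values Non-empty numeric vector of per-frame effective FPS.
#' @return A list of class `fps_summary` with `min`, `mean`, `max`.
#' @export
fps_summary <- function(values) {
  if (length(values) == 0L)
    stop("fps_summary() needs at least one value", call. = FALSE)
  structure(list(min = min(values), mean = mean(values), max = max(values)),
            class = "fps_summary")
}

#' @export
print.fps_summary <- function(x, ...) {
  cat(sprintf("FPS %.2f [%.0f-%.0f] (mean [min-max])\n",
              x$mean, x$min, x$max))
  invisible(x)
}

#' Match counted tracks to ground-truth trajectories
#'
#' Greedy one-to-one matching in order of descending best spatiotemporal
#' overlap: a counted track may match a ground-truth object if on at least
#' one shared frame their boxes overlap with IoU at or above
#' `spatio_iou_min`. Matched events are TP, unmatched events FP, and
#' ground-truth objects never matched FN, so `TP + FN = GT`.
#'
#' @param events Count-event `data.frame` with a `track_id` column.
#' @param track_histories Named list (by track id) of observation
#'   `data.frame`s with columns `frame`, `x`, `y`, `w`, `h`, as returned by
#'   [tracker_histories()].
#' @param gt List of ground-truth trajectories, each a `data.frame` with
#'   columns `frame`, `x`, `y`, `w`, `h`.
#' @param spatio_iou_min Minimum single-frame IoU for a valid match
#'   (default 0.5).
#' @return A [counting_tally()].
#' @export
match_counts_to_gt <- function(events, track_histories, gt,
                               spatio_iou_min = 0.5) {
  ids <- as.character(events$track_id)
  ne <- length(ids); ng <- length(gt)
  best <- matrix(0, ne, ng)
  for (i in seq_len(ne)) {
    th <- track_histories[[ids[i]]]
    if (is.null(th)) next
    for (j in seq_len(ng)) {
      g <- gt[[j]]
      shared <- intersect(th$frame, g$frame)
      if (length(shared) == 0L) next
      a <- th[match(shared, th$frame), , drop = FALSE]
      b <- g[match(shared, g$frame), , drop = FALSE]
      best[i, j] <- max(iou(a, b))
    }
  }
  tp <- 0L
  while (ne > 0L && ng > 0L) {
    top <- max(best)
    if (top < spatio_iou_min) break
    k <- which(best == top, arr.ind = TRUE)[1, ]  # lowest index on ties
    tp <- tp + 1L
    best[k[1], ] <- -1
    best[, k[2]] <- -1
  }
  counting_tally(tp = tp, fp = ne - tp, fn = ng - tp, gt = ng)
}
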