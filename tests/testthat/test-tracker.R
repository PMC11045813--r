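test_that("track initialization converts the box to center/area/aspect", {
  tr <- init_track(boxes(100, 100, 40, 80), 1L)
  expect_equal(tr$kf$x, c(120, 140, 3200, 0.5, 0, 0, 0))
  expect_equal(tr$hits, 1L)
  expect_equal(tr$time_since_update, 0L)
  expect_length(tr$history, 1L)

  sq <- init_track(boxes(0, 0, 10, 10), 2L)
  expect_equal(sq$kf$x[4], 1)  # square box: aspect ratio 1
  expect_false(tr$id == sq$id)
})

test_that("predicting a fresh track returns the initializing box", {
  tr <- init_track(boxes(100, 100, 40, 80), 1L)
  p <- predict_track(tr)
  expect_equal(unlist(p$box[1, 1:4]), c(x = 100, y = 100, w = 40, h = 80))
  expect_equal(p$track$time_since_update, 1L)
  p2 <- predict_track(p$track)
  expect_equal(p2$track$time_since_update, 2L)
})

test_that("the Kalman filter learns constant velocity in the low-noise limit", {
  cfg <- tracker_config(q_diag = rep(0, 7), r_diag = rep(1e-6, 4))
  mats <- trawlcount:::kf_matrices(cfg)
  tr <- init_track(boxes(500, 100, 40, 80), 1L, cfg)
  for (t in 1:10) {
    tr$kf <- trawlcount:::kf_predict(tr$kf, mats)
    z <- trawlcount:::box_to_z(500, 100 + 5 * t, 40, 80)
    tr$kf <- trawlcount:::kf_update(tr$kf, z, mats)
  }
  tr$kf <- trawlcount:::kf_predict(tr$kf, mats)
  # linear extrapolation: center_y = 140 + 5*11
  expect_equal(tr$kf$x[2], 140 + 55, tolerance = 0.5)
  expect_equal(tr$kf$x[6], 5, tolerance = 0.1)
})

test_that("association matches by IoU threshold and partitions inputs", {
  one <- matrix(0.8, 1, 1)
  a <- associate(one, 0.3)
  expect_equal(nrow(a$matches), 1L)
  expect_length(a$unmatched_tracks, 0L)
  expect_length(a$unmatched_dets, 0L)

  low <- matrix(0.1, 1, 1)
  a <- associate(low, 0.3)
  expect_equal(nrow(a$matches), 0L)
  expect_equal(a$unmatched_tracks, 1L)
  expect_equal(a$unmatched_dets, 1L)
})

test_that("association equals the brute-force permutation optimum", {
  # a crafted matrix where greedy row-wise matching is suboptimal
  m <- matrix(c(0.9, 0.8, 0.0,
                0.85, 0.9, 0.0,
                0.0, 0.89, 0.5), 3, 3, byrow = TRUE)
  a <- associate(m, 0.3)
  expect_equal(assoc_total(m, a), brute_best_total(m, 0.3))

  set.seed(99)
  for (k in 1:100) {
    nt <- sample(1:5, 1); nd <- sample(1:5, 1)
    m <- matrix(runif(nt * nd), nt, nd)
    a <- associate(m, 0.3)
    expect_equal(assoc_total(m, a), brute_best_total(m, 0.3),
                 tolerance = 1e-12)
    # conservation at every step
    expect_equal(nrow(a$matches) + length(a$unmatched_dets), nd)
    expect_equal(nrow(a$matches) + length(a$unmatched_tracks), nt)
    expect_true(all(m[a$matches] >= 0.3))
  }
})

test_that("a single noiseless object yields exactly one confirmed track", {
  cfg <- tracker_config()
  tk <- sort_tracker(cfg)
  seen <- integer(0)
  for (f in 0:19) {
    det <- boxes(600, 10 + 5 * f, 60, 40, conf = 0.9)
    st <- tracker_step(tk, det, f)
    tk <- st$tracker
    if (f < cfg$min_hits - 1L) {
      expect_equal(nrow(st$tracks), 0L)  # not yet confirmed
    } else {
      expect_equal(nrow(st$tracks), 1L)  # confirmed from min_hits onward
    }
    seen <- union(seen, st$tracks$track_id)
  }
  expect_length(seen, 1L)
})

test_that("an empty detection stream confirms no tracks", {
  tk <- sort_tracker()
  for (f in 0:9) {
    st <- tracker_step(tk, boxes(), f)
    tk <- st$tracker
    expect_equal(nrow(st$tracks), 0L)
  }
})

test_that("two well-separated objects keep distinct identities", {
  tk <- sort_tracker()
  for (f in 0:29) {
    det <- boxes(x = c(200, 900), y = 10 + 5 * f, w = 60, h = 40,
                 conf = 0.9)
    st <- tracker_step(tk, det, f)
    tk <- st$tracker
  }
  hist <- tracker_histories(tk)
  expect_length(hist, 2L)
  for (h in hist) {
    # each track stays within one lane (lanes are 700 px apart)
    expect_lt(max(h$x) - min(h$x), 100)
  }
  lanes <- sort(unname(vapply(hist, function(h) mean(h$x), numeric(1))))
  expect_equal(lanes, c(200, 900), tolerance = 1)
})

test_that("track lifecycle honors min_hits and max_age", {
  cfg <- tracker_config(min_hits = 3, max_age = 3)
  tk <- sort_tracker(cfg)
  scene <- generate_scene(noisy_config(5L, duration = 10))
  for (f in seq_along(scene$detections) - 1L) {
    st <- tracker_step(tk, scene$detections[[f + 1L]], f)
    tk <- st$tracker
    if (nrow(st$tracks)) {
      expect_true(all(st$tracks$hits >= cfg$min_hits))
      expect_true(all(st$tracks$time_since_update <= cfg$max_age))
    }
  }
})

test_that("out-of-order frames are rejected", {
  tk <- sort_tracker()
  tk <- tracker_step(tk, boxes(), 5)$tracker
  expect_error(tracker_step(tk, boxes(), 5), "increasing")
  expect_error(tracker_step(tk, boxes(), 3), "increasing")
})

test_that("noiseless linear motion is tracked with vanishing prediction error", {
  cfg <- tracker_config()
  mats <- trawlcount:::kf_matrices(cfg)
  tk <- sort_tracker(cfg)
  errs <- numeric(0)
  for (f in 0:29) {
    true_y <- 10 + 6 * f
    # predicted center before the update, from the surviving track
    if (f > 3) {
      tr <- tk$tracks[[1]]
      kf <- trawlcount:::kf_predict(tr$kf, mats)
      errs <- c(errs, abs(kf$x[2] - (true_y + 20)))
    }
    st <- tracker_step(tk, boxes(600, true_y, 60, 40, conf = 0.9), f)
    tk <- st$tracker
  }
  expect_lt(errs[length(errs)], 0.1)
  expect_lt(mean(diff(errs)), 0)  # shrinking after burn-in
})
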