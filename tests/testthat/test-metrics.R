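test_that("correct count rate is 100*TP/GT with GT=0 undefined", {
  expect_equal(correct_count_rate(counting_tally(93, 13, 16, 109)),
               85.32, tolerance = 1e-4)
  expect_equal(correct_count_rate(counting_tally(50, 0, 0, 50)), 100)
  expect_equal(correct_count_rate(counting_tally(0, 0, 10, 10)), 0)
  expect_error(correct_count_rate(counting_tally(0, 0, 0, 0)), "undefined")
})

test_that("F-score weighs false and missed counts together", {
  expect_equal(round(f_score(counting_tally(93, 13, 16, 109)), 2), 0.87)
  expect_equal(round(f_score(counting_tally(78, 11, 31, 109)), 2), 0.79)
  expect_equal(f_score(counting_tally(5, 0, 0, 5)), 1)
  expect_error(f_score(counting_tally(0, 0, 0, 0)), "undefined")
})

test_that("F-score equals the harmonic mean of precision and recall", {
  set.seed(3)
  for (k in 1:50) {
    gt <- sample(5:200, 1)
    tp <- sample(1:gt, 1)
    fp <- sample(0:50, 1)
    t <- counting_tally(tp, fp, gt - tp, gt)
    p <- tp / (tp + fp); r <- tp / gt
    expect_equal(f_score(t), 2 * p * r / (p + r))
  }
})

test_that("correct count rate is scale-invariant", {
  t1 <- counting_tally(9, 2, 3, 12)
  t2 <- counting_tally(36, 2, 12, 48)
  expect_equal(correct_count_rate(t1), correct_count_rate(t2))
})

test_that("fps summaries are elementwise and ordered", {
  s <- fps_summary(c(40, 40, 40))
  expect_equal(c(s$min, s$mean, s$max), c(40, 40, 40))
  s <- fps_summary(c(20, 40))
  expect_equal(c(s$min, s$mean, s$max), c(20, 30, 40))
  expect_true(s$min <= s$mean && s$mean <= s$max)
  expect_error(fps_summary(numeric(0)), "at least one")
})

test_that("perfect detections of three crossing objects give a clean tally", {
  scene <- generate_scene(zero_noise_config(4L, n_objects = 3L))
  rep <- run_pipeline(scene, frame_time = 0.01)
  tally <- match_counts_to_gt(rep$events, rep$track_histories, scene$gt)
  expect_equal(unclass(tally)[c("tp", "fp", "fn", "gt")],
               list(tp = 3L, fp = 0L, fn = 0L, gt = 3L))
})

test_that("no events means all ground truth is missed", {
  t <- match_counts_to_gt(data.frame(track_id = integer()), list(),
                          replicate(4, data.frame(frame = 0L, x = 1, y = 1,
                                                  w = 10, h = 10),
                                    simplify = FALSE))
  expect_equal(c(t$tp, t$fp, t$fn, t$gt), c(0L, 0L, 4L, 4L))
})

test_that("a counted track far from any ground truth is a false positive", {
  gt <- list(data.frame(frame = 0:10, x = 100, y = 100, w = 50, h = 50))
  hist <- list(`7` = data.frame(frame = 0:10, x = 1000, y = 600,
                                w = 50, h = 50))
  t <- match_counts_to_gt(data.frame(track_id = 7L), hist, gt)
  expect_equal(c(t$tp, t$fp, t$fn, t$gt), c(0L, 1L, 1L, 1L))
})

test_that("matching is one-to-one and order-independent", {
  scene <- generate_scene(noisy_config(8L, n_objects = 4L))
  rep <- run_pipeline(scene, frame_time = 0.01)
  t1 <- match_counts_to_gt(rep$events, rep$track_histories, scene$gt)
  t2 <- match_counts_to_gt(rep$events, rep$track_histories, rev(scene$gt))
  expect_equal(unclass(t1), unclass(t2))
  expect_lte(t1$tp, min(nrow(rep$events), length(scene$gt)))
  expect_equal(t1$tp + t1$fn, t1$gt)
})
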