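meta720 <- video_meta(1280, 720, 60, 100L)

test_that("the counting line sits at the configured fraction of frame height", {
  expect_equal(line_y(meta720, counter_config()), 576)
  expect_equal(line_y(video_meta(100, 100, 30), counter_config(line_fraction = 1 / 2)), 50)
})

test_that("bottom-cross fires only on an observed above-to-below transition", {
  expect_true(condition_bottom_cross(boxes(0, 530, 40, 40),
                                     boxes(0, 540, 40, 40), 576))
  expect_false(condition_bottom_cross(boxes(0, 100, 40, 40),
                                      boxes(0, 110, 40, 40), 576))
  # already past the line: no crossing event
  expect_false(condition_bottom_cross(boxes(0, 540, 40, 40),
                                      boxes(0, 550, 40, 40), 576))
})

test_that("center-cross uses the box center with an inclusive below side", {
  expect_true(condition_center_cross(boxes(0, 550, 40, 40),
                                     boxes(0, 560, 40, 40), 576))
  expect_false(condition_center_cross(boxes(0, 480, 40, 40),
                                      boxes(0, 540, 40, 40), 576))
  # landing exactly on the line counts
  expect_true(condition_center_cross(boxes(0, 550, 40, 40),
                                     boxes(0, 556, 40, 40), 576))
})

test_that("tall-box is strict on the height fraction", {
  expect_true(condition_tall_box(boxes(0, 0, 100, 500), meta720))
  expect_false(condition_tall_box(boxes(0, 0, 100, 480), meta720))
  expect_false(condition_tall_box(boxes(0, 0, 100, 100), meta720))
})

test_that("a descending track is counted once, by bottom-cross first", {
  st <- counter_state()
  events <- NULL
  for (f in 0:60) {
    tr <- track_row(1L, 600, 300 + 5 * f, 60, 40)
    up <- update_counts(st, tr, f, meta720)
    st <- up$state
    if (nrow(up$new_events)) events <- rbind(events, up$new_events)
  }
  expect_equal(nrow(st$events), 1L)
  expect_equal(events$condition, "bottom_cross")
  # the box bottom is below its center, so bottom crosses strictly first
  f_cross <- events$frame
  expect_lt(300 + 5 * f_cross + 40, 576 + 45)
})

test_that("hovering above the line is never counted", {
  st <- counter_state()
  for (f in 0:99) {
    st <- update_counts(st, track_row(1L, 600, 100, 60, 40), f, meta720)$state
  }
  expect_equal(nrow(st$events), 0L)
})

test_that("a box inflating past 2/3 frame height fires tall_box above the line", {
  st <- counter_state()
  h <- 100
  for (f in 0:30) {
    h <- h * 1.2
    up <- update_counts(st, track_row(1L, 600, 10, 200, min(h, 504)),
                        f, meta720)
    st <- up$state
    if (nrow(up$new_events)) {
      expect_equal(up$new_events$condition, "tall_box")
      break
    }
  }
  expect_equal(nrow(st$events), 1L)
})

test_that("an already-counted track is never re-counted", {
  st <- counter_state()
  st <- update_counts(st, track_row(1L, 600, 550, 60, 40), 0, meta720)$state
  st <- update_counts(st, track_row(1L, 600, 580, 60, 40), 1, meta720)$state
  expect_equal(nrow(st$events), 1L)
  # keep descending through the line region
  for (f in 2:20) {
    st <- update_counts(st, track_row(1L, 600, 560 + f, 60, 40),
                        f, meta720)$state
  }
  expect_equal(nrow(st$events), 1L)
})

test_that("a track first seen below the line is not counted by default", {
  st <- counter_state()
  for (f in 0:10) {
    st <- update_counts(st, track_row(1L, 600, 600 + 5 * f, 60, 40),
                        f, meta720)$state
  }
  expect_equal(nrow(st$events), 0L)
  # the opt-in flag counts it at first sight
  cfg <- counter_config(count_on_first_sight_below = TRUE)
  st2 <- update_counts(counter_state(), track_row(1L, 600, 600, 60, 40),
                       0, meta720, cfg)$state
  expect_equal(nrow(st2$events), 1L)
})

test_that("predicted-only boxes are ignored unless opted in", {
  st <- counter_state()
  st <- update_counts(st, track_row(1L, 600, 550, 60, 40), 0, meta720)$state
  ghost <- track_row(1L, 600, 580, 60, 40, observed = FALSE)
  st <- update_counts(st, ghost, 1, meta720)$state
  expect_equal(nrow(st$events), 0L)
  cfg <- counter_config(count_on_predicted = TRUE)
  st2 <- counter_state()
  st2 <- update_counts(st2, track_row(1L, 600, 550, 60, 40), 0, meta720, cfg)$state
  st2 <- update_counts(st2, ghost, 1, meta720, cfg)$state
  expect_equal(nrow(st2$events), 1L)
})

test_that("cumulative count is non-decreasing and respects union semantics", {
  full <- counter_config()
  subsets <- list(
    counter_config(enabled_conditions = "bottom_cross"),
    counter_config(enabled_conditions = c("center_cross", "tall_box")),
    counter_config(enabled_conditions = "tall_box"))
  for (seed in 1:3) {
    scene <- generate_scene(noisy_config(seed, duration = 15))
    count_full <- NULL
    prev <- -1
    r_full <- run_pipeline(scene, counter_cfg = full, frame_time = 0.01)
    # monotone cumulative count
    ev <- r_full$events
    if (nrow(ev)) expect_true(all(diff(ev$frame) >= 0))
    for (sub in subsets) {
      r_sub <- run_pipeline(scene, counter_cfg = sub, frame_time = 0.01)
      expect_lte(r_sub$count, r_full$count)
    }
  }
})

test_that("one full crossing is counted for any line position", {
  for (lf in c(0.2, 0.5, 0.8, 0.95)) {
    cfg <- counter_config(line_fraction = lf,
                          enabled_conditions = c("bottom_cross",
                                                 "center_cross"))
    st <- counter_state()
    for (f in 0:160) {
      y <- -40 + 5 * f  # enters above, exits through the bottom
      st <- update_counts(st, track_row(1L, 600, y, 60, 40),
                          f, meta720, cfg)$state
    }
    expect_equal(nrow(st$events), 1L)
  }
})
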