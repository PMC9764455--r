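# Locomotion statistics: velocity, mover classification, head casts.

straight_traj <- function(n = 300, step = 0.01, rate = 30, angle = 0) {
  t_s <- (0:n) / rate
  trajectory(data.frame(
    t_s = t_s,
    x_mm = (0:n) * step * cos(angle),
    y_mm = (0:n) * step * sin(angle)
  ))
}

test_that("average velocity is exact for constant-speed paths", {
  expect_equal(average_velocity(straight_traj(step = 0.01, rate = 30)), 0.3)
  still <- trajectory(data.frame(t_s = 0:10 / 30, x_mm = rep(1, 11),
                                 y_mm = rep(2, 11)))
  expect_equal(average_velocity(still), 0)
  expect_error(trajectory(data.frame(t_s = 0, x_mm = 0, y_mm = 0)),
               "at least 2")
})

test_that("average velocity is invariant under rigid motions and subsampling", {
  tr <- straight_traj(angle = 0.4)
  v0 <- average_velocity(tr)
  # rotation + translation
  th <- 1.1
  rot <- trajectory(data.frame(
    t_s = tr$t_s,
    x_mm = 5 + cos(th) * tr$x_mm - sin(th) * tr$y_mm,
    y_mm = -3 + sin(th) * tr$x_mm + cos(th) * tr$y_mm
  ))
  expect_equal(average_velocity(rot), v0, tolerance = 1e-12)
  # subsample by 2 (straight line: path length unchanged)
  idx <- seq(1, length(tr$t_s), by = 2)
  sub <- trajectory(data.frame(t_s = tr$t_s[idx], x_mm = tr$x_mm[idx],
                               y_mm = tr$y_mm[idx]))
  expect_lt(abs(average_velocity(sub) - v0), 1e-9)
})

test_that("mover classification follows both thresholds", {
  expect_false(classify_moving(trajectory(data.frame(
    t_s = 0:120, x_mm = rep(0, 121), y_mm = rep(0, 121)
  ))))
  # 10 mm net displacement in 120 s
  expect_true(classify_moving(trajectory(data.frame(
    t_s = seq(0, 120, length.out = 121),
    x_mm = seq(0, 10, length.out = 121), y_mm = 0
  ))))
  # generator still larvae are classified still despite jitter
  tj <- gen_trajectories(trajectory_config(n_larvae = 8, still_fraction = 1,
                                           seed = 3))
  movers <- vapply(split_trajectories(tj$table), classify_moving, TRUE)
  expect_false(any(movers))
})

test_that("straight runs and gentle arcs produce no head casts", {
  expect_equal(nrow(detect_head_casts(straight_traj(n = 3600))), 0)

  # open circular arc: heading change per 1 s window = arc angle swept;
  # 30 deg/s stays below the 45 deg threshold
  rate <- 30; omega <- 30 * pi / 180
  t_s <- (0:120) / rate   # 4 s, 120 degrees of arc
  arc <- trajectory(data.frame(
    t_s = t_s,
    x_mm = 3 * cos(omega * t_s), y_mm = 3 * sin(omega * t_s)
  ))
  expect_true(classify_moving(arc))
  expect_equal(nrow(detect_head_casts(arc, max_speed_mm_s = Inf)), 0)

  still <- trajectory(data.frame(t_s = 0:10, x_mm = rep(0, 11),
                                 y_mm = rep(0, 11)))
  expect_error(detect_head_casts(still), "classify")
})

test_that("injected head casts are recovered perfectly without noise", {
  for (s in 1:20) {
    tj <- gen_trajectories(trajectory_config(
      n_larvae = 3, still_fraction = 0, turn_sd_deg = 0, speed_sd_mm_s = 0,
      seed = s
    ))
    sc <- cohort_event_scores(tj)
    expect_equal(sc$recall, 1)
    expect_equal(sc$precision, 1)
  }
})

test_that("recall stays high under strong heading noise", {
  scores <- vapply(1:10, function(s) {
    tj <- gen_trajectories(trajectory_config(
      n_larvae = 5, still_fraction = 0, turn_sd_deg = 10, speed_sd_mm_s = 0,
      seed = 100 + s
    ))
    cohort_event_scores(tj)$recall
  }, 0)
  expect_gte(mean(scores), 0.9)
})

test_that("rate arithmetic and the estimator's calibration hold", {
  expect_equal(events_per_minute(3, 120), 1.5)
  expect_equal(events_per_minute(0, 120), 0)
  expect_equal(events_per_minute(29, 1200), 1.45)

  tj <- gen_trajectories(trajectory_config(n_larvae = 200, still_fraction = 0,
                                           seed = 11))
  beh <- summarize_behavior(tj$table)
  expect_equal(mean(beh$events_per_min[beh$mover]), 1.45, tolerance = 0.1)
})

test_that("trajectory tables round-trip through CSV", {
  tj <- gen_trajectories(trajectory_config(n_larvae = 2, duration_s = 5,
                                           seed = 8))
  f <- tempfile(fileext = ".csv")
  write_trajectories_csv(tj$table, f)
  back <- read_trajectories_csv(f)
  expect_equal(back$x_mm, tj$table$x_mm, tolerance = 1e-9)
  expect_equal(back$larva_id, tj$table$larva_id)
})
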