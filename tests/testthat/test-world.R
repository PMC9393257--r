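test_that("trajectory schedules respect the stated speed and hold ranges", {
  for (seed in c(7, 19, 101)) {
    tr <- generate_trajectory(100, seed = seed)
    expect_true(all(tr$along$speed >= 0 & tr$along$speed <= 10))
    expect_true(all(tr$along$hold %in% 5:10))
    expect_true(all(tr$cross$speed >= 0 & tr$cross$speed <= 4))
    expect_true(all(tr$cross$hold %in% 0:5))
    expect_true(all(tr$cross$sign %in% c(-1L, 1L)))
    expect_gte(sum(tr$along$hold), 100)
    expect_length(tr$along_speed, 100)
  }
  expect_gte(nrow(generate_trajectory(1, seed = 4)$along), 1)
  expect_error(generate_trajectory(0), "positive")
})

test_that("along-track speeds are uniform on [0, 10] in the mean", {
  tr <- generate_trajectory(1e4, seed = 1)
  s <- tr$along$speed
  # oracle: mean of U(0, 10) is 5 with sd 10/sqrt(12)
  se <- (10 / sqrt(12)) / sqrt(length(s))
  expect_lt(abs(mean(s) - 5), 3 * se)
})

test_that("sound duty cycle alternates off 5-10 / on 10-15 starting silent", {
  for (seed in c(3, 11)) {
    ss <- sound_duty_schedule(50, seed = seed)
    expect_true(all(ss$intervals$off %in% 5:10))
    expect_true(all(ss$intervals$on %in% 10:15))
    expect_false(ss$on[1])
    expect_gte(length(ss$on), 50)
  }
  expect_error(sound_duty_schedule(-1), "positive")
})

test_that("long-run on-fraction matches the expected interval lengths", {
  ss <- sound_duty_schedule(2e4, seed = 2)
  # oracle: E[on]/(E[off] + E[on]) = 12.5 / (7.5 + 12.5)
  expect_lt(abs(mean(ss$on[1:2e4]) - 0.625), 0.02)
})

test_that("step_target advances by the scheduled velocities", {
  sched <- structure(list(
    along = data.frame(speed = 2, hold = 10L),
    cross = data.frame(speed = 0, hold = 10L, sign = 1L),
    direction = c(-1, 0),
    along_speed = rep(2, 10), cross_vel = rep(0, 10), n_steps = 10L
  ), class = "trajectory_schedule")
  snd <- structure(list(intervals = data.frame(off = 10L, on = 0L),
                        on = rep(FALSE, 10), n_steps = 10L),
                   class = "sound_schedule")
  s0 <- target_state(c(5, 3), sound_on = FALSE, t = 0L)
  s1 <- step_target(s0, sched, snd, speed_scale = 1)
  expect_equal(s1$position, c(3, 3))  # x decreases by 2 per step
  expect_false(s1$sound_on)           # off-interval active
  expect_equal(s1$t, 1L)

  sched$along_speed <- rep(0, 10)
  expect_equal(step_target(s0, sched, snd, speed_scale = 1)$position, c(5, 3))

  s0$t <- 10L
  expect_error(step_target(s0, sched, snd), "beyond")
})

test_that("vectorized track builder matches iterated step_target", {
  sched <- generate_trajectory(40, seed = 5)
  snd <- sound_duty_schedule(40, seed = 6)
  tr <- crossmodal:::target_track(c(5, 3), sched, snd, 0.005)
  s <- target_state(c(5, 3), t = 0L)
  for (t in 1:40) {
    s <- step_target(s, sched, snd, speed_scale = 0.005)
    expect_equal(unname(tr$position[t + 1, ]), s$position, tolerance = 1e-12)
    expect_identical(tr$sound_on[t], s$sound_on)
  }
})

test_that("track export is reproducible and well-formed", {
  sched <- generate_trajectory(30, seed = 9)
  snd <- sound_duty_schedule(30, seed = 9)
  tab <- track_table(sched, snd)
  expect_equal(names(tab), c("t", "x", "y", "sound_on"))
  expect_equal(nrow(tab), 30)
  expect_identical(generate_trajectory(30, seed = 9)$along,
                   generate_trajectory(30, seed = 9)$along)
})
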