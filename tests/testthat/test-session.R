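advance_all <- function(state, positions, dt = 0.1) {
  wall <- 0
  for (i in seq_len(nrow(positions))) {
    wall <- wall + dt
    state <- progressive_advance(state, input_sample(wall, positions[i, ]))
  }
  state
}

test_that("progressive advances record at the configured pace", {
  s <- session_new(10, session_config("progressive", inter_frame_pause = 0.1))
  s <- advance_all(s, matrix(rep(c(5, 5), 10), ncol = 2, byrow = TRUE),
                   dt = 0.1)
  rec <- session_records(s)
  expect_identical(nrow(rec), 10L)
  expect_equal(diff(rec$wall_time), rep(0.1, 9))
  expect_equal(1 / diff(rec$wall_time), rep(10, 9))  # S = 10 fps
  # stationary cursor over a stationary point: every record identical
  expect_equal(unique(rec$x), 5)
  expect_equal(unique(rec$y), 5)
})

test_that("pause plus processing time of 0.31 s plays at about 3.22 fps", {
  s <- session_new(5, session_config("progressive"))
  s <- advance_all(s, matrix(0, 5, 2), dt = 0.1 + 0.21)
  rec <- session_records(s)
  expect_equal(unique(round(1 / diff(rec$wall_time), 2)), 3.23,
               tolerance = 0.01)
})

test_that("frame-wise clicks advance exactly one frame each", {
  s <- session_new(10, session_config("frame_wise"))
  for (i in 1:4) {
    s <- framewise_click(s, input_sample(i * 0.5, c(i, i), click = TRUE))
  }
  expect_identical(s$current_frame, 4L)
  rec <- session_records(s)
  expect_identical(nrow(rec), 4L)
  expect_equal(1 / diff(rec$wall_time), rep(2, 3))  # dt 0.5 s -> 2 fps
  expect_error(framewise_click(s, input_sample(3, c(0, 0))),
               class = "protrack_data_error")  # click = FALSE
})

test_that("a 1000-frame video requires exactly 1000 clicks", {
  s <- session_new(1000, session_config("frame_wise"))
  for (i in 1:1000) {
    s <- framewise_click(s, input_sample(i * 0.3, c(1, 1), click = TRUE))
  }
  expect_identical(nrow(session_records(s)), 1000L)
  expect_error(
    framewise_click(s, input_sample(1001 * 0.3, c(1, 1), click = TRUE)),
    class = "protrack_session_complete"
  )
})

test_that("rewind overwrites revisited frames and keeps one record per frame", {
  s <- session_new(20, session_config("progressive"))
  s <- advance_all(s, matrix(1, 10, 2))
  expect_identical(rewind(s, 0)$current_frame, s$current_frame)
  s <- rewind(s, 5)
  expect_identical(s$current_frame, 5L)
  wall <- s$last_wall_time
  for (i in 1:5) {
    s <- progressive_advance(s, input_sample(wall + i * 0.1, c(9, 9)))
  }
  rec <- session_records(s)
  expect_identical(nrow(rec), 10L)
  expect_equal(rec$x[1:5], rep(1, 5))   # original positions kept
  expect_equal(rec$x[6:10], rep(9, 5))  # retracked positions overwrite
  expect_error(rewind(s, 11), class = "protrack_bounds_error")
})

test_that("random rewind/advance sequences match the replay oracle", {
  set.seed(42)
  for (rep in 1:200) {
    n <- sample(3:15, 1)
    s <- session_new(n, session_config("progressive"))
    events <- list()
    wall <- 0
    n_ev <- sample(5:30, 1)
    for (k in seq_len(n_ev)) {
      if (runif(1) < 0.75) {
        pos <- runif(2, 0, 50)
        wall <- wall + 0.1
        events[[k]] <- list(type = "advance", pos = pos)
        if (s$current_frame < n) {
          s <- progressive_advance(s, input_sample(wall, pos))
        }
      } else {
        nb <- sample(0:s$current_frame, 1)
        events[[k]] <- list(type = "rewind", n = nb)
        s <- rewind(s, nb)
      }
    }
    oracle <- replay_oracle(n, events)
    rec <- session_records(s)
    expect_identical(nrow(rec), oracle$current)
    expect_identical(anyDuplicated(rec$frame), 0L)
    expect_equal(rec$x, oracle$x)
    expect_equal(rec$y, oracle$y)
  }
})

test_that("wall time must be monotone", {
  s <- session_new(5, session_config("progressive"))
  s <- progressive_advance(s, input_sample(1.0, c(0, 0)))
  expect_error(progressive_advance(s, input_sample(0.5, c(0, 0))),
               class = "protrack_data_error")
})

test_that("screen/video transforms are exact affine inverses", {
  expect_equal(screen_to_video(c(30, 30), zoom = 1, pan = c(0, 0)), c(30, 30))
  expect_equal(screen_to_video(c(30, 30), zoom = 2, pan = c(10, 10)),
               c(25, 25))
  set.seed(7)
  for (i in 1:1000) {
    zoom <- runif(1, 0.1, 10)
    pan <- runif(2, -100, 100)
    p <- runif(2, -500, 500)
    expect_equal(video_to_screen(screen_to_video(p, zoom, pan), zoom, pan),
                 p, tolerance = 1e-9)
  }
  expect_error(screen_to_video(c(0, 0), zoom = 0),
               class = "protrack_config_error")
})

test_that("mode switches are logged per record and ratio is recoverable", {
  s <- session_new(10, session_config("progressive"))
  s <- advance_all(s, matrix(1, 6, 2))
  s <- set_mode(s, "frame_wise")
  wall <- s$last_wall_time
  for (i in 1:4) {
    s <- framewise_click(s, input_sample(wall + i, c(2, 2), click = TRUE))
  }
  rec <- session_records(s)
  expect_identical(rec$mode, c(rep("progressive", 6), rep("frame_wise", 4)))
  expect_equal(mean(rec$mode == "progressive"), 0.6)
})

test_that("halving the pause doubles headless playback speed", {
  run_at <- function(pause) {
    s <- session_new(6, session_config("progressive", inter_frame_pause = pause))
    s <- advance_all(s, matrix(0, 6, 2), dt = pause)
    median(1 / diff(session_records(s)$wall_time))
  }
  expect_equal(run_at(0.05), 2 * run_at(0.1), tolerance = 1e-9)
  expect_error(set_zoom(session_new(3), -1), class = "protrack_config_error")
})
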