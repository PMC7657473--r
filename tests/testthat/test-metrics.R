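test_that("speed is the reciprocal of the capture interval", {
  log <- random_track_log(5)
  log$wall_time <- c(1, 1.5, 2.5, 3.0, 5.0)
  m <- tracking_speed(log)
  expect_equal(m$S, c(NA, 2, 1, 2, 0.5))
  log$wall_time <- rev(log$wall_time)
  expect_error(tracking_speed(log), class = "protrack_data_error")
})

test_that("accuracy uses the Euclidean distance to the true center", {
  truth <- random_truth(3)
  log <- random_track_log(3)
  log$x <- truth$x + c(0, 3, 1)
  log$y <- truth$y + c(0, 4, 0)
  m <- tracking_accuracy(log, truth)
  expect_equal(m$d, c(0, 5, 1))       # 3-4-5 triangle on frame 1
  expect_equal(m$A, 1 / (1 + m$d))
  expect_equal(m$A[1], 1)             # maximal at d = 0
  expect_equal(m$V, truth$v)
  expect_error(tracking_accuracy(dplyr::mutate(log, frame = frame + 100L),
                                 truth),
               class = "protrack_data_error")
})

test_that("accuracy is strictly decreasing, positive and log-safe", {
  d <- c(0, 0.1, 1, 5, 50, 1e6)
  A <- accuracy_score(d)
  expect_true(all(diff(A) < 0))
  expect_true(all(A > 0))
  expect_true(all(is.finite(log(A))))
  expect_error(accuracy_score(-1), class = "protrack_data_error")
})

test_that("paired deltas subtract frame-wise minus progressive, frame-aligned", {
  truth <- random_truth(20)
  fw <- frame_metrics(random_track_log(20, seed = 1, mode = "frame_wise"),
                      truth)
  pr <- frame_metrics(random_track_log(20, seed = 2, mode = "progressive"),
                      truth)
  d <- paired_deltas(fw, pr)
  expect_equal(d$delta_S, d$S_fw - d$S_pr)
  expect_equal(d$delta_A, d$A_fw - d$A_pr)
  # identical logs in both slots: all deltas zero
  d0 <- paired_deltas(fw, fw)
  expect_equal(d0$delta_S, rep(0, nrow(d0)))
  expect_equal(d0$delta_A, rep(0, nrow(d0)))
  # antisymmetry under swapping the inputs
  dsw <- paired_deltas(pr, fw)
  expect_equal(dsw$delta_S, -d$delta_S)
  expect_equal(dsw$delta_A, -d$delta_A)
  # simple arithmetic: S_fw = 1, S_pr = 3 -> delta_S = -2
  expect_equal(unique(paired_deltas(
    dplyr::mutate(fw, S = 1), dplyr::mutate(pr, S = 3))$delta_S), -2)
})

test_that("validity filter uses a strict bound and is idempotent", {
  m <- random_track_log(10)
  m$S <- c(NA, Inf, -1, 0, 0.2, 0.2000001, 0.5, 1, 3, NaN)
  f <- filter_valid(m)
  expect_equal(f$S, c(0.2000001, 0.5, 1, 3))  # 0.2 exactly is removed
  expect_identical(attr(f, "n_removed"), 6L)
  f2 <- filter_valid(f)
  expect_equal(f2$S, f$S)
  expect_identical(attr(f2, "n_removed"), 0L)
  # all-valid input is untouched
  ok <- random_track_log(5)
  ok$S <- 1:5
  expect_equal(filter_valid(ok)$S, 1:5)
})

test_that("surviving counts match a re-scan oracle on randomized tables", {
  set.seed(31)
  for (rep in 1:20) {
    m <- random_track_log(100, seed = rep)
    m$S <- sample(c(runif(80, 0, 5), rep(NA, 5), rep(Inf, 5),
                    rep(0.2, 5), runif(5, -1, 0)))
    kept <- 0L
    for (i in seq_len(nrow(m))) {
      s <- m$S[i]
      if (!is.na(s) && is.finite(s) && s > 0.2) kept <- kept + 1L
    }
    expect_identical(nrow(filter_valid(m)), kept)
  }
})

test_that("precision summarizes spread across repeated trials", {
  base <- random_track_log(10, seed = 1, trial = 1L)
  # all trials identical: sigma 0, P at maximum
  logs <- dplyr::bind_rows(base, dplyr::mutate(base, trial = 2L),
                           dplyr::mutate(base, trial = 3L))
  p <- track_precision(logs)
  expect_equal(p$sigma_x, 0)
  expect_equal(p$P_x, 1)
  expect_equal(p$P_y, 1)
  # two trials offset by a constant in x only
  off <- dplyr::mutate(base, trial = 2L, x = x + 2)
  p2s <- track_precision(dplyr::bind_rows(base, off), sd_type = "sample")
  expect_equal(p2s$sigma_y, 0)
  expect_equal(p2s$sigma_x, 2 / sqrt(2))  # sample SD of two points
  p2p <- track_precision(dplyr::bind_rows(base, off), sd_type = "population")
  expect_equal(p2p$sigma_x, 1)            # half the offset
  expect_error(track_precision(base), class = "protrack_replication_error")
})

test_that("precision on simulated noisy trials equals brute-force SDs", {
  cfg <- small_config(n_frames = 40, seed = 8)
  trj <- simulate_trajectory(cfg)
  agent <- pursuit_agent(gain = 0.7, motor_noise_sd = 1.5)
  logs <- purrr::map_dfr(1:16, function(t) {
    run_trial(trj, agent, session_config("progressive"), trial = t,
              seed = 100 + t)
  })
  pf <- track_precision(logs, by_frame = TRUE)
  for (f in c(0L, 13L, 39L)) {
    xs <- logs$x[logs$frame == f]
    ys <- logs$y[logs$frame == f]
    expect_equal(pf$sigma_x[pf$frame == f], sd(xs))
    expect_equal(pf$P_y[pf$frame == f], 1 / (1 + sd(ys)))
  }
  pooled <- track_precision(logs)
  expect_equal(pooled$sigma_x, mean(pf$sigma_x))
  expect_identical(pooled$n_trials, 16L)
})

test_that("metric pipeline equals brute-force recomputation on random logs", {
  for (seed in 1:5) {
    n <- sample(20:100, 1)
    truth <- random_truth(n, seed = seed + 50)
    log <- random_track_log(n, seed = seed)
    m <- frame_metrics(log, truth)
    s_bf <- bf_speed(log$wall_time)
    a_bf <- bf_accuracy(log$x, log$y, truth$x, truth$y)
    expect_equal(m$S[-1], s_bf[-1], tolerance = 1e-12)
    expect_equal(m$d, a_bf$d, tolerance = 1e-12)
    expect_equal(m$A, a_bf$A, tolerance = 1e-12)
  }
})

test_that("summaries report n, mean, median and quartiles per group", {
  one <- random_track_log(1)
  one$S <- 2; one$A <- 0.5; one$d <- 1
  s <- summarize_metrics(one)
  expect_equal(s$mean[s$metric == "S"], c(2, 2))  # group + pooled
  expect_equal(s$median, s$mean)
  m <- random_track_log(60)
  m$S <- runif(60); m$A <- runif(60); m$d <- runif(60)
  s2 <- summarize_metrics(m, by = "mode")
  pooled <- s2[s2$mode == "pooled" & s2$metric == "S", ]
  expect_equal(pooled$median, median(m$S))
  expect_equal(pooled$q25, unname(quantile(m$S, 0.25)))
  expect_warning(summarize_metrics(m[0, ]), "Empty")
})

test_that("averaging trials first raises accuracy of the averaged track", {
  # averaging cancels motor noise (not systematic lag), so use an agent
  # whose error is noise-dominated
  cfg <- small_config(n_frames = 60, seed = 12)
  trj <- simulate_trajectory(cfg)
  agent <- pursuit_agent(gain = 0.9, motor_noise_sd = 2.5)
  logs <- purrr::map_dfr(1:4, function(t) {
    run_trial(trj, agent, session_config("progressive"), trial = t,
              seed = 200 + t)
  })
  single <- tracking_accuracy(logs, trj)
  avg <- average_trials(logs)
  expect_identical(nrow(avg), 60L)
  merged <- tracking_accuracy(avg, trj)
  # coordinates averaged before computing d
  f0 <- logs[logs$frame == 0, ]
  expect_equal(avg$x[avg$frame == 0], mean(f0$x))
  expect_gt(mean(merged$A), mean(single$A))
})
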