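# Independent brute-force oracles and small fixtures used across tests.
# These deliberately avoid the package's vectorized/grouped code paths:
# plain loops and base R only.

small_config <- function(n_frames = 50, seed = 1, ...) {
  video_config(n_frames = n_frames, frame_width = 200, frame_height = 200,
               seed = seed, ...)
}

# A hand-built random track log (not produced by the session engine).
random_track_log <- function(n = 50, seed = 1, video_id = "v0",
                             user = "u", device = "m", mode = "frame_wise",
                             trial = 1L) {
  set.seed(seed)
  tibble::tibble(
    video_id = video_id, user = user, device = device, mode = mode,
    trial = trial, frame = 0:(n - 1L),
    x = runif(n, 0, 100), y = runif(n, 0, 100),
    wall_time = cumsum(runif(n, 0.05, 1.5))
  )
}

random_truth <- function(n = 50, seed = 2, video_id = "v0") {
  set.seed(seed)
  x <- cumsum(runif(n, -3, 3)) + 50
  y <- cumsum(runif(n, -3, 3)) + 50
  tibble::tibble(
    video_id = video_id, frame = 0:(n - 1L), x = x, y = y,
    v = c(0, sqrt(diff(x)^2 + diff(y)^2))
  )
}

# Loop-based recomputation of per-frame speed for a single trial.
bf_speed <- function(wall_time) {
  n <- length(wall_time)
  s <- rep(NA_real_, n)
  for (i in 2:n) s[i] <- 1 / (wall_time[i] - wall_time[i - 1])
  s
}

# Loop-based Euclidean distance and accuracy.
bf_accuracy <- function(x, y, xt, yt) {
  n <- length(x)
  d <- numeric(n)
  for (i in seq_len(n)) d[i] <- sqrt((x[i] - xt[i])^2 + (y[i] - yt[i])^2)
  list(d = d, A = 1 / (1 + d))
}

# Replay oracle for the session engine: applies a sequence of events
# ("advance" with a position, or "rewind" with a count) to a plain
# array, independent of the tracking_session implementation.
replay_oracle <- function(n_frames, events) {
  x <- rep(NA_real_, n_frames)
  y <- rep(NA_real_, n_frames)
  cur <- 0L
  for (ev in events) {
    if (ev$type == "advance") {
      if (cur >= n_frames) next
      x[cur + 1L] <- ev$pos[1]
      y[cur + 1L] <- ev$pos[2]
      cur <- cur + 1L
    } else {
      cur <- max(0L, cur - ev$n)
    }
  }
  list(x = x[seq_len(cur)], y = y[seq_len(cur)], current = cur)
}

# Simulate delta_S / delta_A data from the piecewise mean functions.
simulate_piecewise_data <- function(n_per_group, pars, eps, seed,
                                    outcome = "delta_S", v_max = 22.8) {
  set.seed(seed)
  purrr::map_dfr(seq_len(nrow(pars)), function(i) {
    V <- runif(n_per_group, 0, v_max)
    mu <- if (outcome == "delta_S") {
      predict_delta_S(V, pars$b[i], pars$c[i], pars$v_crit[i])
    } else {
      predict_delta_A(V, pars$b[i], pars$c[i], pars$v_crit[i])
    }
    out <- tibble::tibble(user = pars$user[i], device = pars$device[i],
                          V = V)
    out[[outcome]] <- rnorm(n_per_group, mu, eps)
    out
  })
}

# Parameter grid for a 2-user x 2-device simulation.
recovery_pars <- function() {
  tibble::tibble(
    user = c("U1", "U1", "U2", "U2"),
    device = c("mouse", "pen", "mouse", "pen"),
    b = c(-2, -1.4, -2.4, -1.8),
    c = c(-0.30, -0.22, -0.38, -0.26),
    v_crit = c(4, 6, 5, 7)
  )
}

# Profile-likelihood grid search for the breakpoint of the delta_S
# form: for each candidate v_crit, b and c are fit by least squares.
grid_search_vcrit <- function(V, y, grid) {
  rss <- vapply(grid, function(vc) {
    z <- (V - vc) * (V <= vc)
    f <- stats::lm(y ~ z)
    sum(stats::resid(f)^2)
  }, numeric(1))
  grid[which.min(rss)]
}
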