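#' Simulated pursuit agent for progressive tracking
#'
#' A first-order cursor-following model: at every displayed frame the
#' cursor moves a fraction `gain` of the way toward the target position
#' seen `reaction_delay` frames ago, plus Gaussian motor noise. With
#' `delay > 0` the cursor lags behind fast-moving targets — for a target
#' moving at constant speed `v` the steady-state lag is
#' `v * (reaction_delay + (1 - gain) / gain)` — which reproduces the
#' velocity-dependent accuracy loss of progressive tracking at fixed
#' playback speed. These agents are synthetic stand-ins for human
#' operators: their contract is the qualitative regime (lag grows with
#' point velocity), not biomechanical realism.
#'
#' @param gain Fraction of the remaining distance covered per frame,
#'   in (0, 1].
#' @param reaction_delay Perception-action delay in frames (>= 0).
#' @param motor_noise_sd Standard deviation of per-frame Gaussian motor
#'   noise, px.
#' @param id Agent identifier (used as the `user` label in logs).
#' @return An object of class `pursuit_agent`.
#' @export
pursuit_agent <- function(gain = 0.6, reaction_delay = 1L,
                          motor_noise_sd = 1, id = "pursuit") {
  if (gain <= 0 || gain > 1) {
    abort("`gain` must be in (0, 1].", class = "protrack_config_error")
  }
  if (reaction_delay < 0) {
    abort("`reaction_delay` must be >= 0.", class = "protrack_config_error")
  }
  if (motor_noise_sd < 0) {
    abort("`motor_noise_sd` must be >= 0.", class = "protrack_config_error")
  }
  structure(list(gain = gain, reaction_delay = as.integer(reaction_delay),
                 motor_noise_sd = motor_noise_sd, id = id),
            class = "pursuit_agent")
}

#' Simulated click agent for frame-wise tracking
#'
#' Click cadence follows a Fitts-law movement-time model: the latency to
#' click the next frame's point grows logarithmically with the distance
#' the cursor has to travel, so frame-wise tracking is fast when the
#' point hardly moves between frames and slows toward a floor as point
#' velocity rises. The distance term saturates at `dist_saturation`,
#' which produces the constant minimum speed observed above a critical
#' point velocity. Click positions get isotropic Gaussian noise of
#' `click_noise_sd`, independent of point velocity.
#'
#' @param base_latency Latency at zero cursor travel, seconds (> 0).
#' @param fitts_slope Seconds per bit of index of difficulty (>= 0).
#' @param target_width Effective target width in px (the point diameter).
#' @param click_noise_sd Click placement noise, px.
#' @param dist_saturation Distance (px) beyond which latency no longer
#'   grows.
#' @param max_speed_cap Upper bound on click rate, frames/second; the
#'   latency is floored at `1 / max_speed_cap`.
#' @param id Agent identifier.
#' @return An object of class `click_agent`.
#' @export
click_agent <- function(base_latency = 0.5, fitts_slope = 0.3,
                        target_width = 13, click_noise_sd = 0.8,
                        dist_saturation = 12, max_speed_cap = 6,
                        id = "click") {
  if (base_latency <= 0) {
    abort("`base_latency` must be > 0.", class = "protrack_config_error")
  }
  if (fitts_slope < 0) {
    abort("`fitts_slope` must be >= 0.", class = "protrack_config_error")
  }
  structure(list(base_latency = base_latency, fitts_slope = fitts_slope,
                 target_width = target_width,
                 click_noise_sd = click_noise_sd,
                 dist_saturation = dist_saturation,
                 max_speed_cap = max_speed_cap, id = id),
            class = "click_agent")
}

#' One step of the pursuit recursion
#'
#' @param cursor Current cursor position (length 2).
#' @param target_history Matrix of true target positions observed so far,
#'   one row per frame, most recent last.
#' @param agent A [pursuit_agent()].
#' @return The new cursor position (length 2). Noise is drawn from the
#'   current RNG stream.
#' @export
pursuit_step <- function(cursor, target_history, agent) {
  n <- nrow(target_history)
  i <- max(1L, n - agent$reaction_delay)
  delayed <- target_history[i, ]
  noise <- if (agent$motor_noise_sd > 0) {
    rnorm(2, sd = agent$motor_noise_sd)
  } else {
    c(0, 0)
  }
  cursor + agent$gain * (delayed - cursor) + noise
}

#' Click latency for a given cursor travel distance
#'
#' `latency = base_latency + fitts_slope * log2(1 + min(d, dist_saturation)
#' / target_width)`, floored at `1 / max_speed_cap`. Strictly increasing
#' in distance below the saturation point (for positive slope), constant
#' above it.
#'
#' @param distance Distance(s) in px the cursor must travel (>= 0).
#' @param agent A [click_agent()].
#' @return Latency in seconds, vectorized over `distance`.
#' @export
click_latency <- function(distance, agent) {
  if (any(distance < 0)) {
    abort("`distance` must be >= 0.", class = "protrack_data_error")
  }
  d <- pmin(distance, agent$dist_saturation)
  lat <- agent$base_latency +
    agent$fitts_slope * log2(1 + d / agent$target_width)
  pmax(lat, 1 / agent$max_speed_cap)
}

#' Run one complete headless tracking trial
#'
#' Drives a [session_new()] session over a full ground-truth trajectory
#' with a simulated agent. Wall time is simulated (pause + processing
#' time in progressive mode; Fitts-law click latency in frame-wise mode),
#' so trials are hardware-independent and fully deterministic given
#' `seed`.
#'
#' @param trajectory Ground-truth tibble from [simulate_trajectory()].
#' @param agent A [pursuit_agent()] (progressive) or [click_agent()]
#'   (frame-wise), matching `config$mode`.
#' @param config A [session_config()].
#' @param video_id,user,device,trial Metadata for the log; `user`
#'   defaults to the agent id.
#' @param seed Integer seed for agent noise.
#' @return A track-log tibble (see [session_records()]) with exactly one
#'   record per frame.
#' @export
run_trial <- function(trajectory, agent, config = session_config(),
                      video_id = "video00", user = agent$id,
                      device = "device", trial = 1L, seed = 1L) {
  mode_needed <- if (inherits(agent, "pursuit_agent")) "progressive"
                 else if (inherits(agent, "click_agent")) "frame_wise"
                 else abort("Unknown agent class.",
                            class = "protrack_config_error")
  if (config$mode != mode_needed) {
    abort(sprintf("Agent of class `%s` requires mode `%s`.",
                  class(agent)[1], mode_needed),
          class = "protrack_config_error")
  }
  cfg_attr <- attr(trajectory, "config")
  fw <- if (!is.null(cfg_attr)) cfg_attr$frame_width else Inf
  fh <- if (!is.null(cfg_attr)) cfg_attr$frame_height else Inf
  n <- nrow(trajectory)
  state <- session_new(n, config, video_id = video_id, user = user,
                       device = device, trial = trial,
                       frame_width = fw, frame_height = fh)
  target <- cbind(trajectory$x, trajectory$y)

  local_seed_eval(seed, {
    if (mode_needed == "progressive") {
      step_time <- config$inter_frame_pause + config$headless_processing_time
      cursor <- target[1, ]
      wall <- 0
      for (f in seq_len(n)) {
        wall <- wall + step_time
        cursor <- pursuit_step(cursor, target[seq_len(f), , drop = FALSE],
                               agent)
        scr <- video_to_screen(cursor, config$zoom, config$pan)
        state <- progressive_advance(state, input_sample(wall, scr))
      }
    } else {
      cursor <- target[1, ]
      wall <- 0
      for (f in seq_len(n)) {
        d <- sqrt(sum((target[f, ] - cursor)^2))
        wall <- wall + click_latency(d, agent)
        click <- target[f, ] + rnorm(2, sd = agent$click_noise_sd)
        scr <- video_to_screen(click, config$zoom, config$pan)
        state <- framewise_click(state, input_sample(wall, scr, click = TRUE))
        cursor <- click
      }
    }
  })
  session_records(state)
}

#' Default simulated users and devices for the benchmark
#'
#' Two simulated users with distinct pursuit and click parameters stand
#' in for two human test persons; two click-agent parameter sets per
#' user emulate the input devices, with the stylus pen given a shorter
#' base latency than the mouse (pen clicking is substantially faster).
#' Defaults were calibrated so that the pooled mean frame-wise speed on
#' the default benchmark is about 1.4 fps.
#'
#' @return A tibble with one row per user x device x mode combination and
#'   a list-column `agent` holding the agent objects.
#' @export
default_agents <- function() {
  grid <- tidyr::expand_grid(
    user = c("U1", "U2"),
    device = c("mouse", "pen"),
    mode = c("progressive", "frame_wise")
  )
  make_agent <- function(user, device, mode) {
    if (mode == "progressive") {
      # Device barely affects smooth pursuit; users differ in lag.
      # At a playback speed of ~3.22 fps one frame lasts ~0.31 s, well
      # above a human reaction time, so the per-frame reaction delay is
      # 0 and lag comes from sub-unity gain: lag = V * (1 - gain) / gain.
      if (user == "U1") {
        pursuit_agent(gain = 0.8, reaction_delay = 0L,
                      motor_noise_sd = 1.2, id = user)
      } else {
        pursuit_agent(gain = 0.62, reaction_delay = 0L,
                      motor_noise_sd = 1.0, id = user)
      }
    } else {
      base <- if (device == "pen") 0.33 else 0.62
      base <- base + if (user == "U1") -0.04 else 0.04
      click_agent(base_latency = base,
                  fitts_slope = if (user == "U1") 0.28 else 0.34,
                  click_noise_sd = if (device == "pen") 0.7 else 0.9,
                  id = user)
    }
  }
  grid$agent <- purrr::pmap(grid, make_agent)
  grid
}

#' Calibrate a click agent's base latency toward a target mean speed
#'
#' Bisects on `base_latency` until the mean frame-wise tracking speed
#' over the supplied trajectories matches `target_mean_fps`.
#'
#' @param target_mean_fps Desired mean frame-wise speed, fps.
#' @param trajectories List of ground-truth trajectories to simulate on.
#' @param agent Template [click_agent()]; all fields except
#'   `base_latency` are kept.
#' @param seed Seed for the simulated trials.
#' @param tol Convergence tolerance on the mean speed, fps.
#' @param max_iter Bisection iteration cap.
#' @return The calibrated [click_agent()].
#' @export
calibrate_click_latency <- function(target_mean_fps, trajectories,
                                    agent = click_agent(), seed = 1L,
                                    tol = 0.01, max_iter = 30L) {
  mean_speed <- function(base) {
    a <- agent
    a$base_latency <- base
    cfg <- session_config(mode = "frame_wise")
    sp <- purrr::map_dbl(seq_along(trajectories), function(i) {
      log <- run_trial(trajectories[[i]], a, cfg,
                       video_id = sprintf("cal%02d", i), seed = seed + i)
      mean(1 / diff(log$wall_time))
    })
    mean(sp)
  }
  lo <- 1e-3
  hi <- 5
  for (i in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    s <- mean_speed(mid)
    if (abs(s - target_mean_fps) < tol) break
    if (s > target_mean_fps) lo <- mid else hi <- mid
  }
  agent$base_latency <- mid
  agent
}
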