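#' Configuration of a tracking session
#'
#' @param mode Tracking mode: `"progressive"` (the cursor is sampled at
#'   every displayed frame while the video plays) or `"frame_wise"` (one
#'   click per frame; the video advances per click).
#' @param inter_frame_pause Configured pause between frames in
#'   progressive mode, seconds (default 0.1). Together with the per-frame
#'   processing time it sets the playback speed: `1 / (pause + processing)`.
#' @param zoom Display zoom factor (> 0).
#' @param pan Video coordinate shown at the screen origin, length-2.
#' @param headless_processing_time Simulated per-frame processing cost in
#'   seconds for non-interactive sessions.
#' @return An object of class `session_config`.
#' @export
session_config <- function(mode = c("progressive", "frame_wise"),
                           inter_frame_pause = 0.1,
                           zoom = 1,
                           pan = c(0, 0),
                           headless_processing_time = 0) {
  mode <- match.arg(mode)
  if (inter_frame_pause < 0) {
    abort("`inter_frame_pause` must be >= 0.", class = "protrack_config_error")
  }
  if (zoom <= 0) {
    abort("`zoom` must be > 0.", class = "protrack_config_error")
  }
  structure(
    list(mode = mode, inter_frame_pause = inter_frame_pause, zoom = zoom,
         pan = as.numeric(pan),
         headless_processing_time = headless_processing_time),
    class = "session_config"
  )
}

#' An input sample from the user (or a simulated agent)
#'
#' @param wall_time Wall-clock time in seconds, non-decreasing within a
#'   session.
#' @param cursor Cursor position in screen coordinates, length-2.
#' @param click Whether this sample is a click.
#' @return An object of class `input_sample`.
#' @export
input_sample <- function(wall_time, cursor, click = FALSE) {
  structure(list(wall_time = wall_time, cursor = as.numeric(cursor),
                 click = isTRUE(click)),
            class = "input_sample")
}

#' Start a tracking session
#'
#' A session digitizes one point of interest over `n_frames` frames and
#' yields exactly one record per frame once complete. Records hold the
#' tracked position in video coordinates, the wall time of capture and
#' the mode active at capture.
#'
#' @param n_frames Number of frames in the video being tracked.
#' @param config A [session_config()].
#' @param video_id,user,device,trial Metadata stored with every record.
#' @param frame_width,frame_height Frame bounds used to clamp recorded
#'   positions (optional; `Inf` disables clamping).
#' @return An object of class `tracking_session`.
#' @export
session_new <- function(n_frames, config = session_config(),
                        video_id = "video", user = "user",
                        device = "device", trial = 1L,
                        frame_width = Inf, frame_height = Inf) {
  n_frames <- as.integer(n_frames)
  if (n_frames < 1L) {
    abort("`n_frames` must be >= 1.", class = "protrack_config_error")
  }
  structure(
    list(
      n_frames = n_frames,
      config = config,
      video_id = video_id, user = user, device = device,
      trial = as.integer(trial),
      frame_width = frame_width, frame_height = frame_height,
      current_frame = 0L,
      x = rep(NA_real_, n_frames),
      y = rep(NA_real_, n_frames),
      wall_time = rep(NA_real_, n_frames),
      mode_used = rep(NA_character_, n_frames),
      last_wall_time = -Inf,
      rewinds = list()
    ),
    class = "tracking_session"
  )
}

#' @export
print.tracking_session <- function(x, ...) {
  cat(sprintf(
    "<tracking_session> %s | user %s | device %s | trial %d\n  mode %s, frame %d / %d\n",
    x$video_id, x$user, x$device, x$trial,
    x$config$mode, x$current_frame, x$n_frames
  ))
  invisible(x)
}

session_is_complete <- function(state) state$current_frame >= state$n_frames

record_sample <- function(state, sample) {
  if (session_is_complete(state)) {
    abort("Session complete: all frames are digitized.",
          class = "protrack_session_complete")
  }
  if (sample$wall_time < state$last_wall_time) {
    abort("`wall_time` must be non-decreasing within a session.",
          class = "protrack_data_error")
  }
  pos <- screen_to_video(sample$cursor, zoom = state$config$zoom,
                         pan = state$config$pan)
  pos[1] <- min(max(pos[1], 0), state$frame_width - 1)
  pos[2] <- min(max(pos[2], 0), state$frame_height - 1)
  i <- state$current_frame + 1L
  state$x[i] <- pos[1]
  state$y[i] <- pos[2]
  state$wall_time[i] <- sample$wall_time
  state$mode_used[i] <- state$config$mode
  state$last_wall_time <- sample$wall_time
  state$current_frame <- state$current_frame + 1L
  state
}

#' Advance a progressive-tracking session by one frame
#'
#' The cursor position at the instant the frame is displayed is mapped to
#' video coordinates and stored for that frame; the playback clock then
#' moves to the next frame.
#'
#' @param state A [session_new()] session in progressive mode.
#' @param sample An [input_sample()].
#' @return The updated session.
#' @export
progressive_advance <- function(state, sample) {
  if (state$config$mode != "progressive") {
    abort("Session is not in progressive mode.",
          class = "protrack_config_error")
  }
  record_sample(state, sample)
}

#' Record a frame-wise click
#'
#' The click position is stored for the displayed frame and the video
#' advances by exactly one frame.
#'
#' @param state A [session_new()] session in frame-wise mode.
#' @param sample An [input_sample()] with `click = TRUE`.
#' @return The updated session.
#' @export
framewise_click <- function(state, sample) {
  if (state$config$mode != "frame_wise") {
    abort("Session is not in frame-wise mode.",
          class = "protrack_config_error")
  }
  if (!sample$click) {
    abort("Frame-wise tracking records only click samples.",
          class = "protrack_data_error")
  }
  record_sample(state, sample)
}

#' Rewind a session to correct earlier frames
#'
#' Moves the playhead back `n_frames_back` frames; subsequent tracking
#' overwrites the previously recorded positions of the re-visited frames,
#' so a completed session still has exactly one record per frame.
#'
#' @param state A session.
#' @param n_frames_back Number of frames to go back (0 is a no-op).
#' @return The updated session.
#' @export
rewind <- function(state, n_frames_back) {
  n_frames_back <- as.integer(n_frames_back)
  if (n_frames_back < 0L || n_frames_back > state$current_frame) {
    abort("Cannot rewind beyond the first frame.",
          class = "protrack_bounds_error")
  }
  if (n_frames_back == 0L) return(state)
  state$current_frame <- state$current_frame - n_frames_back
  state$rewinds <- c(state$rewinds,
                     list(list(at_frame = state$current_frame + n_frames_back,
                               n_back = n_frames_back)))
  state
}

#' Change mode, playback pause or zoom mid-session
#'
#' Changes take effect at the next frame advance; every record keeps the
#' mode that was active when it was captured, so the fraction of
#' progressive-tracked frames per session can be recovered from the log.
#'
#' @param state A session.
#' @param mode,pause,zoom,pan New values.
#' @return The updated session.
#' @export
set_mode <- function(state, mode) {
  state$config$mode <- match.arg(mode, c("progressive", "frame_wise"))
  state
}

#' @rdname set_mode
#' @export
set_playback_pause <- function(state, pause) {
  if (pause < 0) {
    abort("`pause` must be >= 0.", class = "protrack_config_error")
  }
  state$config$inter_frame_pause <- pause
  state
}

#' @rdname set_mode
#' @export
set_zoom <- function(state, zoom, pan = NULL) {
  if (zoom <= 0) {
    abort("`zoom` must be > 0.", class = "protrack_config_error")
  }
  state$config$zoom <- zoom
  if (!is.null(pan)) state$config$pan <- as.numeric(pan)
  state
}

#' Map screen coordinates to video coordinates (and back)
#'
#' The display transform is `screen = (video - pan) * zoom`; these two
#' functions are exact inverses of each other.
#'
#' @param p Length-2 position, or an n x 2 matrix of positions.
#' @param zoom Zoom factor (> 0).
#' @param pan Video coordinate at the screen origin.
#' @return Transformed position(s), same shape as `p`.
#' @export
screen_to_video <- function(p, zoom = 1, pan = c(0, 0)) {
  if (zoom <= 0) abort("`zoom` must be > 0.", class = "protrack_config_error")
  if (is.matrix(p)) {
    sweep(p / zoom, 2, pan, `+`)
  } else {
    pan + p / zoom
  }
}

#' @rdname screen_to_video
#' @export
video_to_screen <- function(p, zoom = 1, pan = c(0, 0)) {
  if (zoom <= 0) abort("`zoom` must be > 0.", class = "protrack_config_error")
  if (is.matrix(p)) {
    sweep(p, 2, pan, `-`) * zoom
  } else {
    (p - pan) * zoom
  }
}

#' Extract the track log of a session
#'
#' @param state A session.
#' @return A tibble with one row per digitized frame (frames `0` to
#'   `current_frame - 1`) and columns
#'   `video_id,user,device,mode,trial,frame,x,y,wall_time`.
#' @export
session_records <- function(state) {
  n <- state$current_frame
  idx <- seq_len(n)
  tibble(
    video_id = rep(state$video_id, n),
    user = rep(state$user, n),
    device = rep(state$device, n),
    mode = state$mode_used[idx],
    trial = rep(state$trial, n),
    frame = idx - 1L,
    x = state$x[idx],
    y = state$y[idx],
    wall_time = state$wall_time[idx]
  )
}
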