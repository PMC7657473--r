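#' Configuration for a synthetic moving-point benchmark video
#'
#' The benchmark emulates test footage for manual digitization: a single
#' bright point on a dark background, moving with random 2D acceleration.
#' The point is a filled disc, slightly blurred at the edges, whose
#' diameter is defined as the full width at half maximum (FWHM) of its
#' intensity profile.
#'
#' @param n_frames Number of frames (default 1000).
#' @param frame_width,frame_height Frame size in px (default 800 x 800).
#' @param point_diameter Nominal point diameter in px, measured as FWHM
#'   (default 13).
#' @param edge_blur_sigma Standard deviation in px of the Gaussian edge
#'   blur (default 1).
#' @param accel_scale Standard deviation of the per-frame Gaussian
#'   acceleration, px/frame^2 (default 1).
#' @param v_max Hard cap on point speed, px/frame (default 22.8). The
#'   velocity vector is rescaled to this norm whenever it would exceed it.
#' @param seed Integer seed; the trajectory is fully deterministic given
#'   the configuration.
#' @param background_intensity,point_intensity 8-bit grayscale levels
#'   (defaults 0 and 255: white point on black).
#'
#' @return An object of class `video_config` (a named list).
#' @examples
#' cfg <- video_config(n_frames = 100, seed = 7)
#' trj <- simulate_trajectory(cfg)
#' max(trj$v) <= cfg$v_max
#' @export
video_config <- function(n_frames = 1000,
                         frame_width = 800,
                         frame_height = 800,
                         point_diameter = 13,
                         edge_blur_sigma = 1,
                         accel_scale = 1,
                         v_max = 22.8,
                         seed = 1L,
                         background_intensity = 0,
                         point_intensity = 255) {
  cfg <- list(
    n_frames = as.integer(n_frames),
    frame_width = as.integer(frame_width),
    frame_height = as.integer(frame_height),
    point_diameter = point_diameter,
    edge_blur_sigma = edge_blur_sigma,
    accel_scale = accel_scale,
    v_max = v_max,
    seed = as.integer(seed),
    background_intensity = background_intensity,
    point_intensity = point_intensity
  )
  class(cfg) <- "video_config"
  validate_video_config(cfg)
  # The drawn disc radius is calibrated so that the *rendered* FWHM of
  # the blurred disc equals `point_diameter`: blurring a convex edge
  # pulls the half-maximum crossing slightly inward, so the drawn radius
  # is a little larger than point_diameter / 2.
  cfg$disc_radius <- calibrate_disc_radius(cfg$point_diameter,
                                           cfg$edge_blur_sigma)
  cfg
}

# Bisect the drawn radius until the continuous rendered profile has the
# requested full width at half maximum.
calibrate_disc_radius <- function(diameter, sigma) {
  target <- diameter
  fwhm_of <- function(r) {
    patch <- disc_patch(r, sigma)
    mid <- (nrow(patch) + 1L) %/% 2L
    measure_fwhm_profile(patch[mid, ])
  }
  lo <- diameter / 2
  hi <- diameter / 2 + 2 * sigma + 0.5
  for (i in 1:30) {
    mid <- (lo + hi) / 2
    if (fwhm_of(mid) < target) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# Continuous (unquantized) coverage patch of a blurred disc centered on
# a pixel center.
disc_patch <- function(r, sigma, ss = 4L) {
  hw <- ceiling(r + 4 * sigma + 1)
  n <- 2L * hw + 1L
  sub <- rep(seq_len(n) - 1L - hw, each = ss) - 0.5 +
    (rep(seq_len(ss), n) - 0.5) / ss
  dist <- sqrt(outer(sub^2, sub^2, `+`))
  cov <- pmin(pmax(0.5 + (r - dist) * ss, 0), 1)
  cov <- matrix(cov, nrow = length(sub))
  if (sigma > 0) cov <- band_convolve(cov, gaussian_kernel(sigma * ss))
  block_mean(cov, ss)
}

# FWHM of a 1D profile with linear interpolation at the half-maximum
# crossings (background assumed 0).
measure_fwhm_profile <- function(profile) {
  half <- max(profile) / 2
  above <- which(profile >= half)
  l <- min(above)
  r <- max(above)
  left_x <- if (l == 1) l - 1 else {
    (l - 1) - (profile[l] - half) / (profile[l] - profile[l - 1])
  }
  right_x <- if (r == length(profile)) r - 1 else {
    (r - 1) + (profile[r] - half) / (profile[r] - profile[r + 1])
  }
  right_x - left_x
}

validate_video_config <- function(cfg) {
  if (cfg$n_frames < 1L) {
    abort("`n_frames` must be >= 1.", class = "protrack_config_error")
  }
  if (cfg$point_diameter <= 0) {
    abort("`point_diameter` must be > 0.", class = "protrack_config_error")
  }
  if (cfg$v_max < 0) {
    abort("`v_max` must be >= 0.", class = "protrack_config_error")
  }
  if (cfg$edge_blur_sigma < 0) {
    abort("`edge_blur_sigma` must be >= 0.", class = "protrack_config_error")
  }
  min_dim <- cfg$point_diameter + 2 * cfg$edge_blur_sigma
  if (cfg$frame_width <= min_dim || cfg$frame_height <= min_dim) {
    abort(
      "Frame dimensions must exceed `point_diameter` + 2 * `edge_blur_sigma`.",
      class = "protrack_config_error"
    )
  }
  invisible(cfg)
}

# Margin (px) the point center keeps from every frame edge, so the blurred
# disc never touches the border.
boundary_margin <- function(cfg) {
  cfg$point_diameter / 2 + 4 * cfg$edge_blur_sigma
}

#' Simulate the ground-truth trajectory of the moving point
#'
#' The point performs a random walk in velocity: i.i.d. Gaussian 2D
#' acceleration of scale `accel_scale` per frame, with the velocity norm
#' clipped to `v_max` and positions reflected at a safety margin inside
#' the frame borders. Per-frame speed `v` is the Euclidean frame-to-frame
#' displacement (`v = 0` for the first frame), so reflections are
#' accounted for exactly.
#'
#' Coordinates are 0-based video pixels: origin at the top-left pixel
#' center, x rightward, y downward, real-valued (subpixel).
#'
#' @param config A [video_config()].
#' @return A tibble with one row per frame and columns `frame` (0-based),
#'   `x`, `y` (px) and `v` (px/frame), with the configuration attached as
#'   attribute `config`.
#' @export
simulate_trajectory <- function(config) {
  validate_video_config(config)
  n <- config$n_frames
  m <- boundary_margin(config)
  lo_x <- m
  hi_x <- (config$frame_width - 1) - m
  lo_y <- m
  hi_y <- (config$frame_height - 1) - m

  pos <- matrix(NA_real_, n, 2)
  pos[1, ] <- c((lo_x + hi_x) / 2, (lo_y + hi_y) / 2)
  vel <- c(0, 0)

  local_seed_eval(config$seed, {
    accel <- matrix(rnorm(2L * max(n - 1L, 0L), sd = config$accel_scale),
                    ncol = 2)
    if (n > 1L) {
      for (f in 2:n) {
        vel <- vel + accel[f - 1L, ]
        spd <- sqrt(sum(vel^2))
        if (spd > config$v_max && spd > 0) {
          # tiny safety factor so the recomputed displacement norm can
          # never exceed the cap through floating-point rounding
          vel <- vel * (config$v_max * (1 - 1e-9) / spd)
        }
        p <- pos[f - 1L, ] + vel
        refl <- reflect_1d(p[1], lo_x, hi_x)
        p[1] <- refl$x
        vel[1] <- vel[1] * refl$sign
        refl <- reflect_1d(p[2], lo_y, hi_y)
        p[2] <- refl$x
        vel[2] <- vel[2] * refl$sign
        pos[f, ] <- p
      }
    }
  })

  v <- c(0, sqrt(rowSums((pos[-1, , drop = FALSE] -
                            pos[-n, , drop = FALSE])^2)))
  if (n == 1L) v <- 0
  out <- tibble(
    frame = 0:(n - 1L),
    x = pos[, 1],
    y = pos[, 2],
    v = v
  )
  attr(out, "config") <- config
  out
}

# Reflect a scalar coordinate into [lo, hi]; returns the reflected value
# and the accumulated sign flip for the velocity component. Reflection
# never increases the distance moved from a point inside the interval.
reflect_1d <- function(x, lo, hi) {
  sign <- 1
  width <- hi - lo
  while (x < lo || x > hi) {
    if (x < lo) x <- 2 * lo - x else x <- 2 * hi - x
    sign <- -sign
    if (width <= 0) {
      x <- lo
      break
    }
  }
  list(x = x, sign = sign)
}

#' Render one video frame
#'
#' Draws the point as an anti-aliased filled disc (4x supersampling with
#' linear edge coverage) convolved with a Gaussian of `edge_blur_sigma`,
#' quantized to 8-bit grayscale. With the default blur the FWHM of the
#' intensity profile through the center equals `point_diameter`.
#'
#' @param trajectory Tibble from [simulate_trajectory()].
#' @param frame_index 0-based frame index.
#' @param config The [video_config()] used to generate `trajectory`.
#' @return An integer matrix (`frame_height` rows x `frame_width`
#'   columns) of 8-bit intensities; `[1, 1]` is the top-left pixel.
#' @export
render_frame <- function(trajectory, frame_index, config) {
  if (frame_index < 0 || frame_index >= config$n_frames) {
    abort("`frame_index` out of range.", class = "protrack_bounds_error")
  }
  row <- trajectory[trajectory$frame == frame_index, ]
  if (nrow(row) != 1L) {
    abort("Frame not present in trajectory.", class = "protrack_bounds_error")
  }
  frame <- matrix(as.integer(round(config$background_intensity)),
                  nrow = config$frame_height, ncol = config$frame_width)
  patch <- render_point_patch(row$x, row$y, config)
  amp <- config$point_intensity - config$background_intensity
  vals <- config$background_intensity + amp * patch$coverage
  vals <- pmin(pmax(round(vals), 0), 255)
  rows <- (patch$y0:patch$y1) + 1L
  cols <- (patch$x0:patch$x1) + 1L
  frame[rows, cols] <- as.integer(vals)
  frame
}

# Render the disc coverage (0..1) on a patch of whole pixels around the
# point center. Supersampled anti-aliased disc, then a separable Gaussian
# blur applied on the supersampled grid via band-matrix multiplication.
render_point_patch <- function(cx, cy, config, ss = 4L) {
  r <- config$disc_radius
  if (is.null(r)) r <- config$point_diameter / 2
  sigma <- config$edge_blur_sigma
  hw <- ceiling(r + 4 * sigma + 1)
  x0 <- max(0L, floor(cx) - hw)
  x1 <- min(config$frame_width - 1L, floor(cx) + hw)
  y0 <- max(0L, floor(cy) - hw)
  y1 <- min(config$frame_height - 1L, floor(cy) + hw)

  # Supersample centers: pixel p spans [p - 0.5, p + 0.5].
  sub_x <- rep(x0:x1, each = ss) - 0.5 + (rep(seq_len(ss), x1 - x0 + 1L) - 0.5) / ss
  sub_y <- rep(y0:y1, each = ss) - 0.5 + (rep(seq_len(ss), y1 - y0 + 1L) - 0.5) / ss

  dx2 <- (sub_x - cx)^2
  dy2 <- (sub_y - cy)^2
  dist <- sqrt(outer(dy2, dx2, `+`))
  # Linear edge coverage over one subpixel width: exact disc area to O(h^2).
  cov <- pmin(pmax(0.5 + (r - dist) * ss, 0), 1)
  cov <- matrix(cov, nrow = length(sub_y))

  if (sigma > 0) {
    k <- gaussian_kernel(sigma * ss)
    cov <- band_convolve(cov, k)
  }
  # Block-mean downsample to whole pixels.
  ny <- (y1 - y0 + 1L)
  nx <- (x1 - x0 + 1L)
  down <- block_mean(cov, ss)
  stopifnot(nrow(down) == ny, ncol(down) == nx)
  list(coverage = down, x0 = x0, x1 = x1, y0 = y0, y1 = y1)
}

gaussian_kernel <- function(sigma) {
  rad <- ceiling(4 * sigma)
  k <- dnorm(seq(-rad, rad), sd = sigma)
  k / sum(k)
}

# Separable 2D convolution by multiplying with band matrices on each side.
band_convolve <- function(m, k) {
  conv_mat <- function(n) {
    rad <- (length(k) - 1L) / 2L
    out <- matrix(0, n, n)
    for (off in seq_along(k)) {
      d <- off - rad - 1L
      idx <- seq_len(n)
      j <- idx + d
      ok <- j >= 1L & j <= n
      out[cbind(idx[ok], j[ok])] <- out[cbind(idx[ok], j[ok])] + k[off]
    }
    out
  }
  conv_mat(nrow(m)) %*% m %*% t(conv_mat(ncol(m)))
}

block_mean <- function(m, ss) {
  ny <- nrow(m) %/% ss
  nx <- ncol(m) %/% ss
  ri <- rep(seq_len(ny), each = ss)
  ci <- rep(seq_len(nx), each = ss)
  t(rowsum(t(rowsum(m, ri)), ci)) / (ss * ss)
}

#' Measure the full width at half maximum of the rendered point
#'
#' Takes the horizontal intensity profile through the brightest pixel,
#' finds where it crosses half of the peak elevation above background
#' (linear interpolation between pixels), and returns the distance
#' between the two crossings in px.
#'
#' @param frame Integer matrix as returned by [render_frame()].
#' @param background Background intensity; defaults to the most common
#'   corner value of the frame.
#' @return FWHM in px (a single number).
#' @export
measure_fwhm <- function(frame, background = NULL) {
  if (is.null(background)) {
    background <- min(frame[1, 1], frame[1, ncol(frame)],
                      frame[nrow(frame), 1], frame[nrow(frame), ncol(frame)])
  }
  # The central chord: the saturated peak can span several rows, so take
  # the row with the largest total intensity rather than the first tie.
  profile <- as.numeric(frame[which.max(rowSums(frame)), ])
  peak <- max(profile)
  half <- background + (peak - background) / 2
  above <- which(profile >= half)
  if (length(above) == 0) {
    abort("No profile values above half maximum.", class = "protrack_data_error")
  }
  l <- min(above)
  r <- max(above)
  # Interpolate the crossing on each flank.
  left_x <- if (l == 1) l - 1 else {
    (l - 1) - (profile[l] - half) / (profile[l] - profile[l - 1])
  }
  right_x <- if (r == length(profile)) r - 1 else {
    (r - 1) + (profile[r] - half) / (profile[r] - profile[r + 1])
  }
  right_x - left_x
}

#' Write a benchmark video to disk
#'
#' Writes the frames as a lossless PNG sequence named
#' `<video_id>_<frame:05d>.png` and the ground-truth trajectory as
#' `<video_id>_truth.csv` (columns `frame,x,y,v`).
#'
#' @param trajectory Tibble from [simulate_trajectory()].
#' @param config The matching [video_config()].
#' @param dir Output directory (created if missing).
#' @param video_id Identifier used as file-name prefix.
#' @param frames Which 0-based frame indices to render (default: all).
#' @return Invisibly, a list with `frame_files` and `truth_file`.
#' @export
write_video <- function(trajectory, config, dir, video_id = "video00",
                        frames = NULL) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  if (is.null(frames)) frames <- trajectory$frame
  files <- character(length(frames))
  for (i in seq_along(frames)) {
    f <- frames[i]
    img <- render_frame(trajectory, f, config)
    files[i] <- file.path(dir, sprintf("%s_%05d.png", video_id, f))
    png::writePNG(img / 255, files[i])
  }
  truth_file <- file.path(dir, paste0(video_id, "_truth.csv"))
  write_trajectory(trajectory, truth_file)
  invisible(list(frame_files = files, truth_file = truth_file))
}

#' Read one PNG frame back as an 8-bit intensity matrix
#'
#' @param path Path to a grayscale PNG written by [write_video()].
#' @return Integer matrix of 8-bit intensities.
#' @export
read_frame <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L) img <- img[, , 1]
  matrix(as.integer(round(img * 255)), nrow = nrow(img))
}
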