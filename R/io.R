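#' Read and write track logs and ground-truth trajectories
#'
#' CSV, comma-separated, UTF-8, header row, '.' decimal, full float
#' precision (shortest round-trip representation), so a write/read cycle
#' reproduces the values bit-exactly.
#'
#' @param track_log,trajectory Tibbles in the package schemas
#'   (`video_id,user,device,mode,trial,frame,x,y,wall_time` and
#'   `frame,x,y,v`).
#' @param path File path.
#' @return The written tibble (invisibly) for writers; a typed tibble
#'   for readers.
#' @export
write_track_log <- function(track_log, path) {
  readr::write_csv(fmt_doubles(track_log), path)
  invisible(track_log)
}

# Format doubles with 17 significant digits so that reading the CSV back
# reproduces the binary values exactly.
fmt_doubles <- function(df) {
  dplyr::mutate(df, across(dplyr::where(is.double),
                           ~ sprintf("%.17g", .x)))
}

#' @rdname write_track_log
#' @export
read_track_log <- function(path) {
  # base read.csv: strtod parses doubles with correct rounding, which
  # the bit-exact round-trip contract requires
  df <- utils::read.csv(path, colClasses = c(
    video_id = "character", user = "character", device = "character",
    mode = "character", trial = "integer", frame = "integer",
    x = "numeric", y = "numeric", wall_time = "numeric"
  ))
  as_tibble(df)
}

#' @rdname write_track_log
#' @export
write_trajectory <- function(trajectory, path) {
  readr::write_csv(fmt_doubles(trajectory[, c("frame", "x", "y", "v")]),
                   path)
  invisible(trajectory)
}

#' @rdname write_track_log
#' @export
read_trajectory <- function(path) {
  df <- utils::read.csv(path, colClasses = c(
    frame = "integer", x = "numeric", y = "numeric", v = "numeric"))
  as_tibble(df)
}

# Candidate source-column names per normalized target column.
supp_candidates <- list(
  video_id = c("video_id", "video", "videoid", "vid"),
  user = c("user", "subject", "person", "tracker", "u"),
  device = c("device", "input_device", "input", "d"),
  mode = c("mode", "method", "tracking_mode", "trackingmethod"),
  trial = c("trial", "rep", "replicate", "repetition"),
  frame = c("frame", "frame_idx", "frameindex", "f", "frame_nr"),
  x = c("x", "x_px", "xtracked", "x_tracked"),
  y = c("y", "y_px", "ytracked", "y_tracked"),
  wall_time = c("wall_time", "time", "t", "timestamp", "time_s"),
  d = c("d", "distance", "dist", "error", "d_px"),
  S = c("s", "speed", "fps", "s_fps", "tracking_speed"),
  A = c("a", "accuracy", "acc", "a_px"),
  V = c("v", "velocity", "point_velocity", "v_px_frame")
)

#' Read supplementary raw tracking tables in flexible layouts
#'
#' Reads a delimited text table of raw per-frame tracking data
#' (delimiter sniffed among comma, semicolon and tab), normalizes column
#' names against a set of documented candidates, and returns a tibble in
#' the package's schema so that all metric functions apply unchanged.
#' The resolved column mapping is attached as attribute `mapping`.
#'
#' @param path Path to the delimited text file.
#' @param schema_map Optional named character vector overriding the
#'   automatic matching, e.g. `c(frame = "FrameNo", x = "PosX")`
#'   (target = source).
#' @param required Target columns that must resolve (default `"frame"`
#'   plus either tracked coordinates or precomputed metrics).
#' @return A normalized tibble containing every target column that
#'   resolved.
#' @export
read_supplementary_tables <- function(path, schema_map = NULL,
                                      required = "frame") {
  first <- readLines(path, n = 1L)
  delims <- c("," = ",", ";" = ";", "\t" = "\t")
  counts <- vapply(delims, function(d) {
    lengths(regmatches(first, gregexpr(d, first, fixed = TRUE)))
  }, integer(1))
  delim <- delims[[which.max(counts)]]
  raw <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           trim_ws = TRUE)
  norm <- function(x) gsub("[^a-z0-9_]", "", tolower(x))
  src_norm <- norm(names(raw))

  mapping <- character(0)
  for (target in names(supp_candidates)) {
    src <- NA_character_
    if (!is.null(schema_map) && target %in% names(schema_map)) {
      hit <- match(norm(schema_map[[target]]), src_norm)
      if (is.na(hit)) {
        abort(sprintf("Mapped column `%s` for `%s` not found in file.",
                      schema_map[[target]], target),
              class = "protrack_schema_error")
      }
      src <- names(raw)[hit]
    } else {
      hit <- match(norm(supp_candidates[[target]]), src_norm)
      hit <- hit[!is.na(hit)]
      if (length(hit)) src <- names(raw)[hit[1]]
    }
    if (!is.na(src)) mapping[target] <- src
  }

  missing_req <- setdiff(required, names(mapping))
  has_positions <- all(c("x", "y") %in% names(mapping))
  has_metrics <- any(c("d", "S", "A") %in% names(mapping))
  if (length(missing_req) || !(has_positions || has_metrics)) {
    abort(paste0(
      "Could not resolve required columns. Missing: ",
      paste(union(missing_req,
                  if (!(has_positions || has_metrics)) "x/y or d/S/A"),
            collapse = ", "),
      ". Found columns: ", paste(names(raw), collapse = ", "),
      ". Recognized candidates per target: ",
      paste(vapply(names(supp_candidates), function(t) {
        paste0(t, "={", paste(supp_candidates[[t]], collapse = "|"), "}")
      }, character(1)), collapse = "; ")),
      class = "protrack_schema_error")
  }
  out <- raw[, unname(mapping), drop = FALSE]
  names(out) <- names(mapping)
  out <- as_tibble(out)
  if ("mode" %in% names(out)) {
    out$mode <- normalize_mode(out$mode)
  }
  attr(out, "mapping") <- mapping
  out
}

normalize_mode <- function(mode) {
  m <- tolower(as.character(mode))
  dplyr::case_when(
    grepl("^(fw|frame)", m) ~ "frame_wise",
    grepl("^(pr|prog)", m) ~ "progressive",
    TRUE ~ m
  )
}

#' Row counts per tracking mode, before and after the validity filter
#'
#' Reports sample sizes per mode both for all rows with defined speed
#' and after the finite `S > min_fps` filter, since published counts may
#' refer to either stage.
#'
#' @param metrics Per-frame metrics tibble with `mode` and `S`.
#' @param min_fps Filter threshold (default 0.2 fps).
#' @return A tibble with `mode, n_defined, n_valid`.
#' @export
count_rows_by_mode <- function(metrics, min_fps = 0.2) {
  metrics %>%
    group_by(.data$mode) %>%
    summarise(
      n_defined = sum(is.finite(.data$S)),
      n_valid = sum(is.finite(.data$S) & .data$S > min_fps),
      .groups = "drop"
    )
}

#' Describe a full simulated benchmark
#'
#' The default manifest mirrors the benchmark design: ten 1000-frame
#' videos of a moving point, each digitized with all four methods (two
#' modes x two devices) by each of two simulated users — 40 trials per
#' user, 80,000 tracked frames in total. Trial order is randomized (and
#' the permutation recorded) so video and method alternate between
#' trials. All randomness derives from the single `seed` via named
#' substreams (video generation, agents, trial order), so every stage
#' can be reproduced independently.
#'
#' @param n_videos Number of benchmark videos (default 10).
#' @param n_frames Frames per video (default 1000).
#' @param agents Agent grid, see [default_agents()].
#' @param reps Replications of every video x method x user combination
#'   (default 1).
#' @param seed Master seed.
#' @param inter_frame_pause Progressive-mode pause, s (default 0.1).
#' @param processing_time Simulated per-frame processing cost, s
#'   (default 0.21, i.e. a playback speed of about 3.22 fps).
#' @param video_config_args Extra arguments passed to [video_config()].
#' @return An object of class `benchmark_manifest`: a trial-table tibble
#'   with attributes holding the configuration.
#' @export
benchmark_manifest <- function(n_videos = 10L, n_frames = 1000L,
                               agents = default_agents(), reps = 1L,
                               seed = 1L,
                               inter_frame_pause = 0.1,
                               processing_time = 0.21,
                               video_config_args = list()) {
  seeds <- derive_seeds(seed, 3L)
  video_ids <- sprintf("video%02d", seq_len(n_videos) - 1L)
  trials <- tidyr::expand_grid(
    video_id = video_ids,
    agents,
    rep = seq_len(reps)
  )
  # Randomized trial order, recorded as a permutation.
  perm <- withr::with_seed(seeds[3], sample.int(nrow(trials)))
  trials <- trials[perm, ]
  trials$trial <- seq_len(nrow(trials))
  trials$seed <- derive_seeds(seeds[2], nrow(trials))

  structure(
    trials,
    class = c("benchmark_manifest", class(trials)),
    n_videos = n_videos, n_frames = n_frames, seed = seed,
    video_seed = seeds[1], order_permutation = perm,
    inter_frame_pause = inter_frame_pause,
    processing_time = processing_time,
    video_config_args = video_config_args
  )
}

#' Run the full simulated benchmark
#'
#' Strings the pipeline together: generate ground-truth trajectories,
#' simulate every tracking trial in the manifest, compute per-frame
#' metrics, apply the validity filter, and build the frame-aligned
#' paired differences. Optionally writes the artifact tree (ground
#' truth, track logs, metrics, deltas, manifest) as CSV files.
#'
#' @param manifest A [benchmark_manifest()].
#' @param out_dir Optional output directory for the artifact tree.
#' @param min_fps Validity filter threshold (default 0.2 fps).
#' @param render If `TRUE`, also write PNG frames for every video
#'   (slow; off by default since analyses use the trajectories).
#' @return An object of class `benchmark_result`: a list with
#'   `trajectories` (named list), `logs`, `metrics`, `metrics_valid`,
#'   `deltas` (tibbles) and `manifest`.
#' @export
run_benchmark <- function(manifest, out_dir = NULL, min_fps = 0.2,
                          render = FALSE) {
  n_videos <- attr(manifest, "n_videos")
  n_frames <- attr(manifest, "n_frames")
  video_seeds <- derive_seeds(attr(manifest, "video_seed"), n_videos)
  video_ids <- sprintf("video%02d", seq_len(n_videos) - 1L)

  cfg_args <- attr(manifest, "video_config_args")
  trajectories <- lapply(seq_len(n_videos), function(i) {
    cfg <- do.call(video_config, c(
      list(n_frames = n_frames, seed = video_seeds[i]), cfg_args))
    simulate_trajectory(cfg)
  })
  names(trajectories) <- video_ids

  logs <- purrr::map_dfr(seq_len(nrow(manifest)), function(i) {
    tr <- manifest[i, ]
    scfg <- session_config(
      mode = tr$mode,
      inter_frame_pause = attr(manifest, "inter_frame_pause"),
      headless_processing_time = attr(manifest, "processing_time")
    )
    run_trial(trajectories[[tr$video_id]], tr$agent[[1]], scfg,
              video_id = tr$video_id, user = tr$user, device = tr$device,
              trial = tr$trial, seed = tr$seed)
  })

  truth <- purrr::map_dfr(video_ids, function(vid) {
    mutate(trajectories[[vid]], video_id = vid)
  })
  metrics <- frame_metrics(logs, truth)
  metrics_valid <- filter_valid(metrics, min_fps = min_fps)
  deltas <- paired_deltas(
    filter(metrics_valid, .data$mode == "frame_wise"),
    filter(metrics_valid, .data$mode == "progressive")
  )

  result <- structure(
    list(trajectories = trajectories, logs = logs, metrics = metrics,
         metrics_valid = metrics_valid, deltas = deltas,
         manifest = manifest),
    class = "benchmark_result"
  )

  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    for (vid in video_ids) {
      write_trajectory(trajectories[[vid]],
                       file.path(out_dir, paste0(vid, "_truth.csv")))
      if (render) {
        cfg <- attr(trajectories[[vid]], "config")
        write_video(trajectories[[vid]], cfg,
                    file.path(out_dir, "frames"), video_id = vid)
      }
    }
    write_track_log(logs, file.path(out_dir, "track_log.csv"))
    readr::write_csv(metrics, file.path(out_dir, "metrics.csv"))
    readr::write_csv(deltas, file.path(out_dir, "deltas.csv"))
    manifest_flat <- manifest
    manifest_flat$agent <- vapply(
      manifest_flat$agent,
      function(a) paste0(class(a)[1], ":", a$id), character(1))
    readr::write_csv(as_tibble(manifest_flat),
                     file.path(out_dir, "manifest.csv"))
  }
  result
}

#' @export
print.benchmark_result <- function(x, ...) {
  cat(sprintf(
    "<benchmark_result> %d videos x %d frames, %d trials, %d tracked frames\n  valid frames: %d; paired frames: %d\n",
    attr(x$manifest, "n_videos"), attr(x$manifest, "n_frames"),
    nrow(x$manifest), nrow(x$logs), nrow(x$metrics_valid), nrow(x$deltas)))
  invisible(x)
}
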