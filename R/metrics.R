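#' Inverse-distance accuracy and inverse-spread precision scores
#'
#' Accuracy maps the Euclidean error `d` (px) of a tracked position to
#' `A = 1 / (1 + d)` in px^-1: strictly decreasing in `d`, finite and
#' positive everywhere (so `log(A)` is always defined), and equal to 1
#' at a perfect hit. Precision applies the same map to the standard
#' deviation of repeated trials: `P = 1 / (1 + sigma)`.
#'
#' @param d Euclidean distance(s) in px, >= 0.
#' @param sigma Standard deviation(s) in px, >= 0.
#' @return Score(s) in px^-1, in (0, 1].
#' @export
accuracy_score <- function(d) {
  if (any(d < 0, na.rm = TRUE)) {
    abort("`d` must be >= 0.", class = "protrack_data_error")
  }
  1 / (1 + d)
}

#' @rdname accuracy_score
#' @export
precision_score <- function(sigma) {
  if (any(sigma < 0, na.rm = TRUE)) {
    abort("`sigma` must be >= 0.", class = "protrack_data_error")
  }
  1 / (1 + sigma)
}

trial_keys <- c("video_id", "user", "device", "trial")

#' Per-frame tracking speed
#'
#' Speed is the reciprocal of the interval between consecutive frame
#' captures: `S_f = 1 / (t_f - t_{f-1})` in digitized frames per second
#' of operator time. The first frame of each trial has no preceding
#' capture, so its `S` is `NA` (dropped later by [filter_valid()]).
#'
#' @param track_log Track-log tibble with columns
#'   `video_id,user,device,trial,frame,wall_time` (and usually `mode`).
#' @return The input with columns `dt` (s) and `S` (fps) added.
#' @export
tracking_speed <- function(track_log) {
  keys <- intersect(trial_keys, names(track_log))
  out <- track_log %>%
    group_by(across(all_of(keys))) %>%
    arrange(.data$frame, .by_group = TRUE) %>%
    mutate(dt = c(NA_real_, diff(.data$wall_time)),
           S = 1 / .data$dt) %>%
    ungroup()
  if (any(out$dt < 0, na.rm = TRUE)) {
    abort("`wall_time` must be monotone within a trial.",
          class = "protrack_data_error")
  }
  out
}

#' Per-frame tracking accuracy
#'
#' Computes the Euclidean distance `d` between each tracked position and
#' the true point center, the accuracy `A = 1 / (1 + d)`, and attaches
#' the instantaneous point velocity `V` from the ground truth.
#'
#' @param track_log Track-log tibble (columns include `frame,x,y`).
#' @param ground_truth Ground-truth tibble with columns `frame,x,y,v`
#'   for the same video, or with a `video_id` column covering several
#'   videos.
#' @return The input with columns `d` (px), `A` (px^-1) and `V`
#'   (px/frame) added.
#' @export
tracking_accuracy <- function(track_log, ground_truth) {
  truth <- ground_truth %>%
    rename(x_true = "x", y_true = "y", V = "v")
  keys <- intersect(c("video_id", "frame"), names(truth))
  joined <- left_join(track_log, truth, by = keys)
  if (anyNA(joined$x_true)) {
    abort("Ground truth is missing for some tracked frames.",
          class = "protrack_data_error")
  }
  joined %>%
    mutate(d = sqrt((.data$x - .data$x_true)^2 + (.data$y - .data$y_true)^2),
           A = accuracy_score(.data$d)) %>%
    select(-"x_true", -"y_true")
}

#' Per-frame speed and accuracy in one call
#'
#' @inheritParams tracking_speed
#' @inheritParams tracking_accuracy
#' @return A per-frame metrics tibble with `d`, `S`, `A` and `V`.
#' @export
frame_metrics <- function(track_log, ground_truth) {
  track_log %>%
    tracking_speed() %>%
    tracking_accuracy(ground_truth)
}

#' Frame-aligned paired differences between tracking modes
#'
#' Because both modes digitize identical frames, performance is compared
#' within frames: `delta_S = S_fw - S_pr` and `delta_A = A_fw - A_pr`,
#' paired by video, user, device and frame. Point velocity `V` comes
#' from the ground truth (identical in both inputs).
#'
#' @param metrics_fw,metrics_pr Per-frame metrics tibbles (from
#'   [frame_metrics()]) for the frame-wise and progressive trials of the
#'   same videos, users and devices.
#' @return A tibble with columns
#'   `video_id,user,device,frame,V,delta_S,delta_A` plus the per-mode
#'   `S` and `A` columns, one row per frame present and valid in both
#'   modes.
#' @export
paired_deltas <- function(metrics_fw, metrics_pr) {
  keys <- intersect(c("video_id", "user", "device", "frame"),
                    intersect(names(metrics_fw), names(metrics_pr)))
  if (!"frame" %in% keys) {
    abort("Inputs must share a `frame` column.", class = "protrack_data_error")
  }
  fw <- metrics_fw %>%
    select(all_of(keys), S_fw = "S", A_fw = "A", V_fw = "V")
  pr <- metrics_pr %>%
    select(all_of(keys), S_pr = "S", A_pr = "A", V_pr = "V")
  if (anyDuplicated(fw[keys]) || anyDuplicated(pr[keys])) {
    abort(paste0("Multiple records per (", paste(keys, collapse = ","),
                 "): average or subset trials before pairing."),
          class = "protrack_data_error")
  }
  out <- inner_join(fw, pr, by = keys)
  # defined only where both modes have finite metrics for the frame
  out <- filter(out, is.finite(.data$S_fw), is.finite(.data$S_pr),
                is.finite(.data$A_fw), is.finite(.data$A_pr))
  if (any(abs(out$V_fw - out$V_pr) > 1e-9, na.rm = TRUE)) {
    abort("Ground-truth velocities disagree between the two inputs.",
          class = "protrack_data_error")
  }
  out %>%
    mutate(V = .data$V_fw,
           delta_S = .data$S_fw - .data$S_pr,
           delta_A = .data$A_fw - .data$A_pr) %>%
    select(-"V_fw", -"V_pr")
}

#' Validity filter on tracking speed
#'
#' Keeps only frames with finite `S` strictly greater than `min_fps`
#' (default 0.2 fps), removing first-frame records (undefined `S`) and
#' implausibly slow captures that reflect computational stalls rather
#' than tracking. Idempotent. The number of removed rows is attached as
#' attribute `n_removed`.
#'
#' @param metrics Per-frame metrics tibble with a speed column.
#' @param min_fps Exclusive lower bound on `S` (default 0.2).
#' @param col Name of the speed column (default `"S"`; use `"S_fw"` /
#'   `"S_pr"` on paired tables, or both via two calls).
#' @return The filtered tibble.
#' @export
filter_valid <- function(metrics, min_fps = 0.2, col = "S") {
  s <- metrics[[col]]
  if (is.null(s)) {
    abort(sprintf("Column `%s` not found.", col),
          class = "protrack_data_error")
  }
  keep <- is.finite(s) & s > min_fps
  out <- metrics[keep, , drop = FALSE]
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' Tracking precision across repeated trials
#'
#' Precision measures reproducibility: how close repeated digitizations
#' of the same point are to each other, independent of the (possibly
#' unknown) true position. Per frame, the standard deviation of the
#' tracked x- and y-coordinates across trials is computed; the pooled
#' sigma per group is the mean of the per-frame standard deviations, and
#' `P = 1 / (1 + sigma)` in px^-1.
#'
#' @param track_log Track log containing >= 2 trials per group.
#' @param by Grouping columns identifying one tracked point (default
#'   `"video_id"`).
#' @param sd_type `"sample"` (n - 1 denominator, default) or
#'   `"population"` (n).
#' @param by_frame If `TRUE`, return per-frame sigma and P instead of the
#'   pooled summary.
#' @return A tibble with `sigma_x, sigma_y, P_x, P_y, n_trials` per
#'   group (pooled) or per group and frame (`by_frame = TRUE`).
#' @export
track_precision <- function(track_log, by = "video_id",
                            sd_type = c("sample", "population"),
                            by_frame = FALSE) {
  sd_type <- match.arg(sd_type)
  sd_fun <- function(z) {
    n <- sum(!is.na(z))
    if (sd_type == "sample") sd(z) else sd(z) * sqrt((n - 1) / n)
  }
  by <- intersect(by, names(track_log))
  per_frame <- track_log %>%
    group_by(across(all_of(c(by, "frame")))) %>%
    summarise(n_trials = dplyr::n(),
              sigma_x = sd_fun(.data$x),
              sigma_y = sd_fun(.data$y),
              .groups = "drop")
  if (any(per_frame$n_trials < 2L)) {
    abort("Precision requires >= 2 trials per frame.",
          class = "protrack_replication_error")
  }
  per_frame <- per_frame %>%
    mutate(P_x = precision_score(.data$sigma_x),
           P_y = precision_score(.data$sigma_y))
  if (by_frame) return(per_frame)
  per_frame %>%
    group_by(across(all_of(by))) %>%
    summarise(n_trials = min(.data$n_trials),
              sigma_x = mean(.data$sigma_x),
              sigma_y = mean(.data$sigma_y),
              .groups = "drop") %>%
    mutate(P_x = precision_score(.data$sigma_x),
           P_y = precision_score(.data$sigma_y))
}

#' Average repeated trials into a single track
#'
#' Averages the tracked coordinates per frame across trials (coordinates
#' first, metrics afterwards), yielding one consensus track whose
#' accuracy can then be compared with single-trial accuracy. Averaging
#' repeated progressive trials reduces noise and raises accuracy.
#'
#' @param track_log Track log with >= 2 trials per group.
#' @param by Grouping columns identifying one tracked point.
#' @return A track-log tibble with one row per group and frame,
#'   `trial = 0` and mean `wall_time`.
#' @export
average_trials <- function(track_log, by = c("video_id", "user", "device",
                                             "mode")) {
  by <- intersect(by, names(track_log))
  track_log %>%
    group_by(across(all_of(c(by, "frame")))) %>%
    summarise(x = mean(.data$x), y = mean(.data$y),
              wall_time = mean(.data$wall_time),
              .groups = "drop") %>%
    mutate(trial = 0L)
}

#' Summary statistics per group and pooled
#'
#' Median, mean and quartiles of selected metric columns, per grouping
#' combination and pooled over all rows.
#'
#' @param metrics Per-frame metrics tibble.
#' @param vars Metric columns to summarize (default those of
#'   `c("S", "A", "d")` that are present).
#' @param by Grouping columns (default those of
#'   `c("mode", "device", "user")` that are present).
#' @return A long tibble with columns `metric`, the grouping columns
#'   (`"pooled"` rows aggregate everything), `n, mean, median, q25, q75`.
#' @export
summarize_metrics <- function(metrics, vars = c("S", "A", "d"),
                              by = c("mode", "device", "user")) {
  if (nrow(metrics) == 0) {
    warn("Empty metrics table; nothing to summarize.")
    return(tibble())
  }
  vars <- intersect(vars, names(metrics))
  by <- intersect(by, names(metrics))
  one <- function(df, label_cols) {
    purrr::map_dfr(vars, function(v) {
      z <- df[[v]]
      z <- z[is.finite(z)]
      tibble(metric = v, n = length(z),
             mean = mean(z), median = median(z),
             q25 = quantile(z, 0.25, names = FALSE),
             q75 = quantile(z, 0.75, names = FALSE)) %>%
        dplyr::bind_cols(label_cols)
    })
  }
  pooled <- one(metrics, tibble(!!!setNames(
    rep(list("pooled"), length(by)), by)))
  grouped <- metrics %>%
    dplyr::group_split(across(all_of(by))) %>%
    purrr::map_dfr(function(df) {
      one(df, df[1, by, drop = FALSE])
    })
  bind_rows(grouped, pooled)
}
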