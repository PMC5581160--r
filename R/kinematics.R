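# Kinematic descriptor panel. Two thresholds with distinct semantics:
# a fly is "in motion" strictly above the 2.5 mm/s cutoff, while a walking
# episode ("trajectory") is a maximal run of frames at or above the 2 mm/s
# walk threshold (speeds below 2 mm/s are not progressive movement).
# Vial totals are normalized by the detection-derived fly count so vials
# with different survivor numbers stay comparable.

#' Per-frame speed trace of a track
#'
#' Raw speed between consecutive points (`||p[i+1] - p[i]|| * fps`),
#' smoothed by a centred moving average of `window_frames` frames
#' (truncated at the ends). Smoothing suppresses the pixel-quantization
#' jitter that would otherwise inflate motion descriptors.
#'
#' @param track Data frame of one fly's positions (`frame`, `x_mm`,
#'   `y_mm`), at least 2 points with uniform frame spacing.
#' @param fps Frame rate in frames per second.
#' @param window_frames Odd moving-average window length (1 = no smoothing).
#' @return Data frame of class `speed_trace` with `frame` (index of the
#'   interval start), `speed_mm_s` (smoothed), `step_mm` (raw per-frame
#'   displacement); attributes `window_frames` and `fps`.
#' @export
compute_speed_trace <- function(track, fps, window_frames = 5L) {
  check_scalar_number(fps, "fps", 0, strict_min = TRUE)
  window_frames <- check_count(window_frames, "window_frames", 1L)
  if (window_frames %% 2L == 0L)
    stop_vt("'window_frames' must be odd (got %d)", window_frames)
  n <- nrow(track)
  if (n < 2L) stop_vt("speed trace needs at least 2 track points")
  df <- diff(track$frame)
  if (any(df != df[1L]))
    stop_vt("track frames must be uniformly spaced (interpolate gaps first)")
  step <- sqrt(diff(track$x_mm)^2 + diff(track$y_mm)^2)
  raw <- step * fps / df[1L]
  h <- (window_frames - 1L) %/% 2L
  smoothed <- if (h == 0L) raw else {
    # truncated centred moving average via cumulative sums
    cs <- c(0, cumsum(raw))
    m <- length(raw)
    lo <- pmax(seq_len(m) - h, 1L)
    hi <- pmin(seq_len(m) + h, m)
    (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  }
  structure(
    data.frame(frame = track$frame[-n], speed_mm_s = smoothed, step_mm = step),
    class = c("speed_trace", "data.frame"),
    window_frames = window_frames, fps = fps)
}

#' Percentage of time in motion
#'
#' Fraction of speed frames strictly above the cutoff, pooled over all
#' traces of a vial, as a percentage. "Strictly above" means a fly moving
#' exactly at the cutoff is not in motion.
#'
#' @param traces A `speed_trace` or list of them.
#' @param cutoff_mm_s Motion cutoff in mm/s (default 2.5).
#' @return Percentage in `[0, 100]`.
#' @export
percent_in_motion <- function(traces, cutoff_mm_s = 2.5) {
  check_scalar_number(cutoff_mm_s, "cutoff_mm_s", 0)
  if (inherits(traces, "speed_trace")) traces <- list(traces)
  if (!length(traces)) stop_vt("at least one speed trace is required")
  speeds <- unlist(lapply(traces, `[[`, "speed_mm_s"), use.names = FALSE)
  100 * sum(speeds > cutoff_mm_s + SPEED_TOL) / length(speeds)
}

#' Segment walking episodes from a speed trace
#'
#' Maximal runs of consecutive frames with speed at or above
#' `walk_threshold_mm_s` become episodes; runs shorter than
#' `min_episode_s` are discarded as flicker. The episode path length is
#' the sum of the raw per-frame displacements inside the run.
#'
#' @param trace A `speed_trace` from [compute_speed_trace()].
#' @param walk_threshold_mm_s Walk threshold in mm/s (default 2).
#' @param min_episode_s Minimum episode duration in seconds retained.
#' @param fps Frame rate; taken from the trace attribute if omitted.
#' @return Data frame with `start_frame`, `end_frame`, `duration_s`,
#'   `path_length_mm`, one row per episode.
#' @export
segment_walk_episodes <- function(trace, walk_threshold_mm_s = 2,
                                  min_episode_s = 0.2, fps = NULL) {
  check_scalar_number(walk_threshold_mm_s, "walk_threshold_mm_s", 0)
  check_scalar_number(min_episode_s, "min_episode_s", 0)
  if (is.null(fps)) fps <- attr(trace, "fps")
  check_scalar_number(fps, "fps", 0, strict_min = TRUE)
  on <- trace$speed_mm_s >= walk_threshold_mm_s - SPEED_TOL
  r <- rle(on)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & (r$lengths / fps >= min_episode_s - 1e-12)
  starts <- starts[keep]; ends <- ends[keep]
  data.frame(
    start_frame = trace$frame[starts],
    end_frame = trace$frame[ends],
    duration_s = (ends - starts + 1L) / fps,
    path_length_mm = vapply(seq_along(starts), function(i)
      sum(trace$step_mm[starts[i]:ends[i]]), numeric(1)))
}

#' Summarise one vial recording into the kinetic descriptor panel
#'
#' Computes speed traces and walking episodes for every track in one
#' recording of one vial and aggregates them into the eight-descriptor
#' panel. Velocities are pooled over all speed frames (robust to identity
#' switches, which only re-partition the pooled set); totals are divided by
#' the detection-derived fly count where the descriptor is per-fly.
#'
#' @param tracks Track data frame for one vial (from [build_tracks()] or
#'   ground truth).
#' @param fly_count Number of flies in the vial (from [count_flies()]).
#' @param fps Frame rate in frames per second.
#' @param params List overriding `walk_threshold_mm_s`,
#'   `motion_cutoff_mm_s`, `window_frames`, `min_episode_s` (defaults from
#'   [default_config()]).
#' @return One-row data frame of class `vial_kinetics`: `vial_id`,
#'   `fly_count`, `mean_velocity_mm_s`, `max_velocity_mm_s`,
#'   `total_walking_duration_s` (per fly), `total_walking_distance_mm`
#'   (vial total), `percent_time_in_motion`, `mean_trajectory_length_mm`
#'   (per fly), `mean_trajectory_length_per_episode_mm`, `n_trajectories`
#'   (episode count), `mean_trajectories_per_fly`.
#' @export
summarize_vial <- function(tracks, fly_count, fps, params = list()) {
  defaults <- default_config()
  p <- utils::modifyList(
    defaults[c("walk_threshold_mm_s", "motion_cutoff_mm_s",
               "window_frames", "min_episode_s")], params)
  fly_count <- check_count(fly_count, "fly_count", 0L)
  if (fly_count == 0L && nrow(tracks) > 0L)
    stop_vt("fly_count is 0 but tracks are non-empty")
  vial <- if (nrow(tracks)) tracks$vial_id[1L] else NA_integer_
  if (nrow(tracks) && length(unique(tracks$vial_id)) > 1L)
    stop_vt("summarize_vial() expects tracks from a single vial")

  groups <- if (nrow(tracks)) split(tracks, tracks$fly_id) else list()
  groups <- groups[vapply(groups, nrow, integer(1)) >= 2L]
  traces <- lapply(groups, compute_speed_trace, fps = fps,
                   window_frames = p$window_frames)
  episodes <- lapply(traces, segment_walk_episodes,
                     walk_threshold_mm_s = p$walk_threshold_mm_s,
                     min_episode_s = p$min_episode_s, fps = fps)
  speeds <- unlist(lapply(traces, `[[`, "speed_mm_s"), use.names = FALSE)
  ep <- do.call(rbind, episodes)
  n_ep <- if (is.null(ep)) 0L else nrow(ep)
  total_dist <- if (n_ep) sum(ep$path_length_mm) else 0
  total_dur <- if (n_ep) sum(ep$duration_s) else 0
  div <- max(fly_count, 1L)

  structure(data.frame(
    vial_id = vial,
    fly_count = fly_count,
    mean_velocity_mm_s = if (length(speeds)) mean(speeds) else 0,
    max_velocity_mm_s = if (length(speeds)) max(speeds) else 0,
    total_walking_duration_s = total_dur / div,
    total_walking_distance_mm = total_dist,
    percent_time_in_motion = if (length(speeds))
      percent_in_motion(traces, p$motion_cutoff_mm_s) else 0,
    mean_trajectory_length_mm = total_dist / div,
    mean_trajectory_length_per_episode_mm = if (n_ep) total_dist / n_ep else 0,
    n_trajectories = n_ep,
    mean_trajectories_per_fly = n_ep / div
  ), class = c("vial_kinetics", "data.frame"))
}

#' Average two replicate recordings of a vial
#'
#' Field-wise arithmetic mean of all descriptors across the two recordings
#' of the same vial (acquired one after the other). The recorded fly count
#' is the smaller of the two; if they differ the result carries
#' `attr(, "unequal_fly_count") = TRUE`.
#'
#' @param a,b `vial_kinetics` rows for the same `vial_id`.
#' @return A `vial_kinetics` row.
#' @export
average_replicates <- function(a, b) {
  if (a$vial_id != b$vial_id)
    stop_vt("cannot average replicates of different vials (%s vs %s)",
            a$vial_id, b$vial_id)
  out <- a
  num <- setdiff(names(a)[vapply(a, is.numeric, logical(1))],
                 c("vial_id", "fly_count"))
  for (f in num) out[[f]] <- (a[[f]] + b[[f]]) / 2
  out$fly_count <- min(a$fly_count, b$fly_count)
  if (a$fly_count != b$fly_count) attr(out, "unequal_fly_count") <- TRUE
  out
}
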