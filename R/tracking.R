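# Fly tracking mode: links per-frame detections into identities by optimal
# (minimum total distance) assignment with gating, tolerates short
# detection gaps by linear interpolation, and discards spurious short
# tracks.

# O(n^3) Hungarian method (Jonker-Volgonant style potentials with shortest
# augmenting paths) for an n x m cost matrix with n <= m. Returns, for each
# row, the assigned column index. Written here rather than taken from a
# library because optimal gated assignment is the core of the tracking
# contract; the test suite checks it against brute-force permutation
# enumeration and an independent LSAP solver.
hungarian_lsap <- function(a) {
  n <- nrow(a); m <- ncol(a)
  if (n > m) stop_vt("hungarian_lsap() needs nrow <= ncol")
  if (n == 0L) return(integer(0))
  u <- numeric(n + 1L)        # row potentials, index r+1 (row 0 virtual)
  v <- numeric(m + 1L)        # col potentials, index c+1 (col 0 virtual)
  p <- integer(m + 1L)        # p[c+1]: row currently assigned to col c
  way <- integer(m + 1L)      # alternating-path back-pointers
  for (i in seq_len(n)) {
    p[1L] <- i
    j0 <- 0L
    minv <- rep(Inf, m)
    used <- rep(FALSE, m + 1L)
    repeat {
      used[j0 + 1L] <- TRUE
      i0 <- p[j0 + 1L]
      free_j <- which(!used[-1L])
      cur <- a[i0, free_j] - u[i0 + 1L] - v[free_j + 1L]
      upd <- cur < minv[free_j]
      if (any(upd)) {
        minv[free_j[upd]] <- cur[upd]
        way[free_j[upd] + 1L] <- j0
      }
      j1 <- free_j[which.min(minv[free_j])]
      delta <- minv[j1]
      uc <- which(used) - 1L
      u[p[uc + 1L] + 1L] <- u[p[uc + 1L] + 1L] + delta
      v[uc + 1L] <- v[uc + 1L] - delta
      minv[free_j] <- minv[free_j] - delta
      j0 <- j1
      if (p[j0 + 1L] == 0L) break
    }
    repeat {
      j1 <- way[j0 + 1L]
      p[j0 + 1L] <- p[j1 + 1L]
      j0 <- j1
      if (j0 == 0L) break
    }
  }
  assignment <- integer(n)
  for (j in seq_len(m)) if (p[j + 1L] > 0L) assignment[p[j + 1L]] <- j
  assignment
}

# Cost placed on pairs outside the gate; large enough to dominate any sum
# of real distances so feasible matches are always preferred.
GATE_BIG <- 1e9

#' Gated optimal assignment of detections to predicted positions
#'
#' Finds the matching between predicted track positions and observed
#' detections that minimises total Euclidean distance, subject to every
#' matched pair lying within `gate_mm`. Solved exactly with the Hungarian
#' method; pairs beyond the gate and surplus items on either side are
#' returned unmatched.
#'
#' @param predicted Two-column matrix or data frame (`x_mm`, `y_mm`) of
#'   predicted positions, one row per live track.
#' @param observed Data frame of detections with `cx_mm`, `cy_mm`.
#' @param gate_mm Gating radius in mm (must be >= 0).
#' @return List with `pairs` (data frame `predicted`, `observed`,
#'   `distance_mm` of row indices), `unmatched_predicted`,
#'   `unmatched_observed` (integer index vectors).
#' @export
assign_detections <- function(predicted, observed, gate_mm) {
  if (!is.numeric(gate_mm) || length(gate_mm) != 1L || is.na(gate_mm) || gate_mm < 0)
    stop_vt("'gate_mm' must be a single non-negative number")
  pm <- as.matrix(as.data.frame(predicted)[, 1:2, drop = FALSE])
  om <- cbind(observed$cx_mm, observed$cy_mm)
  np <- nrow(pm); no <- nrow(om)
  empty <- data.frame(predicted = integer(0), observed = integer(0),
                      distance_mm = numeric(0))
  if (np == 0L || no == 0L)
    return(list(pairs = empty, unmatched_predicted = seq_len(np),
                unmatched_observed = seq_len(no)))
  d <- sqrt(outer(pm[, 1L], om[, 1L], `-`)^2 + outer(pm[, 2L], om[, 2L], `-`)^2)
  cost <- ifelse(d <= gate_mm, d, GATE_BIG)
  k <- max(np, no)
  sq <- matrix(0, k, k)
  sq[seq_len(np), seq_len(no)] <- cost
  sol <- hungarian_lsap(sq)
  pred_idx <- seq_len(np)
  obs_idx <- sol[pred_idx]
  ok <- obs_idx <= no & cost[cbind(pred_idx, pmin(obs_idx, no))] < GATE_BIG
  pairs <- data.frame(predicted = pred_idx[ok], observed = obs_idx[ok],
                      distance_mm = d[cbind(pred_idx[ok], obs_idx[ok])])
  list(pairs = pairs,
       unmatched_predicted = pred_idx[!ok],
       unmatched_observed = setdiff(seq_len(no), pairs$observed))
}

#' Build fly tracks from per-frame detections
#'
#' Frame-by-frame nearest-identity tracking: each live track predicts its
#' next position as its last observed position (constant-position model;
#' at 30 fps inter-frame motion is small relative to inter-fly spacing),
#' detections are matched by [assign_detections()] with a gate of
#' `gate_mm_per_s / fps` per elapsed frame, unmatched detections open new
#' tracks, tracks unseen for more than `max_gap_frames` frames close, gaps
#' up to `max_gap_frames` are filled by linear interpolation (flagged), and
#' tracks spanning fewer than `min_track_frames` points are discarded.
#'
#' @param detections Detection data frame (one or more vials; tracked
#'   independently per vial). Frames must be sorted non-decreasingly.
#' @param fps Frame rate in frames per second.
#' @param params List with `gate_mm_per_s`, `max_gap_frames`,
#'   `min_track_frames`; defaults from [default_config()].
#' @return Data frame of class `fly_tracks`: `vial_id`, `fly_id` (unique
#'   within vial, in order of track creation), `frame`, `t_s`, `x_mm`,
#'   `y_mm`, `interpolated`.
#' @export
build_tracks <- function(detections, fps, params = list()) {
  check_scalar_number(fps, "fps", 0, strict_min = TRUE)
  defaults <- default_config()
  p <- utils::modifyList(
    defaults[c("gate_mm_per_s", "max_gap_frames", "min_track_frames")], params)
  if (is.unsorted(detections$frame))
    stop_vt("detections must be sorted by frame")
  per_vial <- lapply(split(detections, detections$vial_id), function(d)
    build_tracks_vial(d, fps, p))
  out <- do.call(rbind, per_vial)
  if (is.null(out))
    out <- data.frame(vial_id = integer(0), fly_id = integer(0),
                      frame = integer(0), t_s = numeric(0), x_mm = numeric(0),
                      y_mm = numeric(0), interpolated = logical(0))
  rownames(out) <- NULL
  structure(out, class = c("fly_tracks", "data.frame"))
}

build_tracks_vial <- function(d, fps, p) {
  vial <- d$vial_id[1L]
  gate1 <- p$gate_mm_per_s / fps
  frames <- min(d$frame):max(d$frame)
  by_frame <- split(d, factor(d$frame, levels = frames))
  active <- list()   # each: list(frame=, x=, y=, interp=, last_frame, last_x, last_y)
  finished <- list()
  for (f in frames) {
    obs <- by_frame[[as.character(f)]]
    n_obs <- if (is.null(obs)) 0L else nrow(obs)
    if (length(active)) {
      last_f <- vapply(active, `[[`, numeric(1), "last_frame")
      # close tracks whose gap can no longer be bridged
      open <- which(f - last_f <= p$max_gap_frames + 1L)
      finished <- c(finished, active[setdiff(seq_along(active), open)])
      active <- active[open]
    }
    if (n_obs == 0L) next
    matched_obs <- integer(0)
    if (length(active)) {
      pred <- cbind(vapply(active, `[[`, numeric(1), "last_x"),
                    vapply(active, `[[`, numeric(1), "last_y"))
      gaps <- f - vapply(active, `[[`, numeric(1), "last_frame")
      # one joint assignment; gate grows with the elapsed interval, so use
      # the per-track maximum and re-check each pair against its own gate
      m <- assign_detections(pred, obs, gate1 * max(gaps))
      if (nrow(m$pairs)) {
        keep <- m$pairs$distance_mm <= gate1 * gaps[m$pairs$predicted]
        m$pairs <- m$pairs[keep, , drop = FALSE]
      }
      for (r in seq_len(nrow(m$pairs))) {
        ti <- m$pairs$predicted[r]; oi <- m$pairs$observed[r]
        tr <- active[[ti]]
        gap <- f - tr$last_frame
        if (gap > 1L) {
          mid <- (tr$last_frame + 1L):(f - 1L)
          w <- (mid - tr$last_frame) / gap
          tr$frame <- c(tr$frame, mid)
          tr$x <- c(tr$x, tr$last_x + w * (obs$cx_mm[oi] - tr$last_x))
          tr$y <- c(tr$y, tr$last_y + w * (obs$cy_mm[oi] - tr$last_y))
          tr$interp <- c(tr$interp, rep(TRUE, length(mid)))
        }
        tr$frame <- c(tr$frame, f)
        tr$x <- c(tr$x, obs$cx_mm[oi])
        tr$y <- c(tr$y, obs$cy_mm[oi])
        tr$interp <- c(tr$interp, FALSE)
        tr$last_frame <- f; tr$last_x <- obs$cx_mm[oi]; tr$last_y <- obs$cy_mm[oi]
        active[[ti]] <- tr
        matched_obs <- c(matched_obs, oi)
      }
    }
    for (oi in setdiff(seq_len(n_obs), matched_obs)) {
      active[[length(active) + 1L]] <- list(
        frame = f, x = obs$cx_mm[oi], y = obs$cy_mm[oi], interp = FALSE,
        last_frame = f, last_x = obs$cx_mm[oi], last_y = obs$cy_mm[oi])
    }
  }
  finished <- c(finished, active)
  finished <- finished[vapply(finished, function(t) length(t$frame),
                              integer(1)) >= p$min_track_frames]
  if (!length(finished)) return(NULL)
  # stable fly ids in order of track creation (first frame, then encounter)
  ord <- order(vapply(finished, function(t) t$frame[1L], numeric(1)))
  finished <- finished[ord]
  do.call(rbind, lapply(seq_along(finished), function(i) {
    t <- finished[[i]]
    data.frame(vial_id = vial, fly_id = i, frame = as.integer(t$frame),
               t_s = t$frame / fps, x_mm = t$x, y_mm = t$y,
               interpolated = t$interp)
  }))
}
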