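# Fixture builders and independent oracles used across the suite.

# Straight-line track at constant speed v (mm/s): frames 0..duration_s*fps,
# moving along a 45-degree diagonal so both coordinates exercise the norm.
straight_track <- function(v, duration_s = 10, fps = 30, vial_id = 1L,
                           fly_id = 1L) {
  n <- as.integer(round(duration_s * fps)) + 1L
  step <- v / fps / sqrt(2)
  data.frame(vial_id = vial_id, fly_id = fly_id, frame = 0:(n - 1L),
             t_s = (0:(n - 1L)) / fps,
             x_mm = cumsum(c(0, rep(step, n - 1L))),
             y_mm = cumsum(c(0, rep(step, n - 1L))))
}

# Stationary ground-truth table for rendering tests: one row per fly per
# frame of a short recording.
stationary_tracks <- function(positions, config) {
  n_frames <- as.integer(round(config$duration_s * config$fps)) + 1L
  do.call(rbind, lapply(seq_len(nrow(positions)), function(i) {
    data.frame(vial_id = 1L, fly_id = i, frame = 0:(n_frames - 1L),
               t_s = (0:(n_frames - 1L)) / config$fps,
               x_mm = positions$x[i], y_mm = positions$y[i],
               walking = FALSE)
  }))
}

# Reference flood-fill connected-component counter (8-connectivity) on a
# logical matrix; deliberately naive and independent of the package's
# union-find labelling.
flood_count <- function(mask) {
  seen <- matrix(FALSE, nrow(mask), ncol(mask))
  count <- 0L
  for (r0 in seq_len(nrow(mask))) for (c0 in seq_len(ncol(mask))) {
    if (!mask[r0, c0] || seen[r0, c0]) next
    count <- count + 1L
    queue <- list(c(r0, c0)); seen[r0, c0] <- TRUE
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      for (dr in -1:1) for (dc in -1:1) {
        r <- p[1] + dr; c <- p[2] + dc
        if (r >= 1 && r <= nrow(mask) && c >= 1 && c <= ncol(mask) &&
            mask[r, c] && !seen[r, c]) {
          seen[r, c] <- TRUE
          queue[[length(queue) + 1]] <- c(r, c)
        }
      }
    }
  }
  count
}

# Brute-force minimum-cost perfect matching over all permutations; the
# stated oracle for the Hungarian assignment (n <= 7).
brute_force_min_cost <- function(d) {
  n <- nrow(d)
  stopifnot(n == ncol(d), n <= 7)
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
    out
  }
  min(vapply(perms(seq_len(n)), function(p) sum(d[cbind(seq_len(n), p)]),
             numeric(1)))
}

# Count identity switches of tracked output against ground truth: each
# tracked point is matched to the nearest ground-truth fly in its frame;
# a switch is a change of matched identity within one track.
count_identity_switches <- function(tracks, truth) {
  switches <- 0L
  for (tr in split(tracks, tracks$fly_id)) {
    ids <- vapply(seq_len(nrow(tr)), function(i) {
      g <- truth[truth$frame == tr$frame[i], ]
      g$fly_id[which.min((g$x_mm - tr$x_mm[i])^2 + (g$y_mm - tr$y_mm[i])^2)]
    }, integer(1))
    switches <- switches + sum(diff(ids) != 0)
  }
  switches
}
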