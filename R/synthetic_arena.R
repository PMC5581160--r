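# Synthetic arena: a stochastic pause/walk model of flies climbing in
# vertical vials, and a renderer that turns the resulting ground-truth
# trajectories into camera frames. Everything downstream (detection,
# tracking, kinematics) can be validated against the exported truth.

#' Simulation configuration
#'
#' Parameters of the synthetic multi-vial arena. Protocol constants follow
#' the standard negative-geotaxis recording: four 75 x 13 mm vials, ten
#' flies per vial, 10 s of video at 30 frames/s from a fixed 640 x 480
#' camera, with the rack tapped immediately before recording so an upward
#' geotaxis drift acts throughout.
#'
#' Motion is a two-state (pause/walk) Markov chain per fly: each frame a
#' paused fly starts walking with probability `p_start_walk` and a walking
#' fly stops with `p_stop_walk`. A walking episode carries a speed drawn
#' once from a positive-truncated normal; headings persist between frames
#' (`heading_persistence` = 1 means straight lines) and walls reflect.
#'
#' `min_separation_mm` > 0 enforces non-overlapping flies by rejection:
#' initial positions are re-drawn and moves that would bring two flies
#' closer than the limit are rejected. The default (2.5 mm) keeps rendered
#' blobs disjoint so detection counts are unambiguous; set 0 to allow
#' overlap/occlusion.
#'
#' @param n_vials Number of vials in the rack.
#' @param flies_per_vial Flies per vial at the start of the recording.
#' @param duration_s Recording length in seconds.
#' @param fps Frame rate, frames per second.
#' @param tube_length_mm,tube_width_mm Inner tube dimensions in mm.
#' @param p_start_walk,p_stop_walk Per-frame state-flip probabilities.
#' @param walk_speed_mean_mm_s,walk_speed_sd_mm_s Episode speed
#'   distribution (normal truncated at 0), mm/s.
#' @param heading_persistence In `[0, 1]`; weight of the previous heading
#'   when blended with a fresh uniform heading each walking frame.
#' @param geotaxis_drift_mm_s Upward drift (mm/s) applied to walking flies,
#'   modelling the post-startle climb; active for the whole recording.
#' @param blob_radius_px Rendered fly disc radius, pixels.
#' @param background_level,fly_level 8-bit intensities of the lit tube and
#'   of a fly (flies are dark on a bright tube).
#' @param noise_sd Additive Gaussian pixel noise standard deviation.
#' @param min_separation_mm Minimum allowed pairwise fly distance (0 = off).
#' @param seed Integer seed; the same seed gives bit-identical trajectories
#'   and frames.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_vials = 4L,
                       flies_per_vial = 10L,
                       duration_s = 10,
                       fps = 30,
                       tube_length_mm = 75,
                       tube_width_mm = 13,
                       p_start_walk = 0.2,
                       p_stop_walk = 0.05,
                       walk_speed_mean_mm_s = 8,
                       walk_speed_sd_mm_s = 2,
                       heading_persistence = 0.8,
                       geotaxis_drift_mm_s = 2,
                       blob_radius_px = 3,
                       background_level = 200,
                       fly_level = 40,
                       noise_sd = 3,
                       min_separation_mm = 2.5,
                       seed = 1L) {
  cfg <- list(
    n_vials = check_count(n_vials, "n_vials", 1L),
    flies_per_vial = check_count(flies_per_vial, "flies_per_vial", 0L),
    duration_s = check_scalar_number(duration_s, "duration_s", 0, strict_min = TRUE),
    fps = check_scalar_number(fps, "fps", 0, strict_min = TRUE),
    tube_length_mm = check_scalar_number(tube_length_mm, "tube_length_mm", 0, strict_min = TRUE),
    tube_width_mm = check_scalar_number(tube_width_mm, "tube_width_mm", 0, strict_min = TRUE),
    p_start_walk = check_probability(p_start_walk, "p_start_walk"),
    p_stop_walk = check_probability(p_stop_walk, "p_stop_walk"),
    walk_speed_mean_mm_s = check_scalar_number(walk_speed_mean_mm_s, "walk_speed_mean_mm_s", 0, strict_min = TRUE),
    walk_speed_sd_mm_s = check_scalar_number(walk_speed_sd_mm_s, "walk_speed_sd_mm_s", 0),
    heading_persistence = check_probability(heading_persistence, "heading_persistence"),
    geotaxis_drift_mm_s = check_scalar_number(geotaxis_drift_mm_s, "geotaxis_drift_mm_s", 0),
    blob_radius_px = check_scalar_number(blob_radius_px, "blob_radius_px", 0, strict_min = TRUE),
    background_level = check_scalar_number(background_level, "background_level", 0, 255),
    fly_level = check_scalar_number(fly_level, "fly_level", 0, 255),
    noise_sd = check_scalar_number(noise_sd, "noise_sd", 0),
    min_separation_mm = check_scalar_number(min_separation_mm, "min_separation_mm", 0),
    seed = check_count(seed, "seed")
  )
  if (cfg$fly_level >= cfg$background_level)
    stop_vt("'fly_level' must be < 'background_level' (dark flies on a bright tube)")
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "<sim_config> %d vial(s) x %d flies, %.3g s @ %.3g fps, tube %g x %g mm, seed %d\n",
    x$n_vials, x$flies_per_vial, x$duration_s, x$fps,
    x$tube_width_mm, x$tube_length_mm, x$seed))
  invisible(x)
}

# Positive-truncated normal episode speeds by rejection.
draw_episode_speed <- function(n, mean, sd) {
  if (n == 0L) return(numeric(0))
  if (sd == 0) return(rep(mean, n))
  out <- rnorm(n, mean, sd)
  bad <- which(out <= 0)
  while (length(bad)) {
    out[bad] <- rnorm(length(bad), mean, sd)
    bad <- bad[out[bad] <= 0]
  }
  out
}

#' Simulate ground-truth fly trajectories
#'
#' Runs the pause/walk Markov model for every fly in every vial and returns
#' the trajectories at frame resolution. Initial walk states are drawn from
#' the chain's stationary distribution
#' `p_start_walk / (p_start_walk + p_stop_walk)`, so with `p_start_walk = 0`
#' every fly starts (and stays) paused.
#'
#' @param config A [sim_config()] object.
#' @return A data frame of class `gt_tracks` with one row per fly per frame
#'   and columns `vial_id`, `fly_id`, `frame` (0-based), `t_s`, `x_mm`,
#'   `y_mm` (height above tube bottom), `walking`. Each fly contributes
#'   `duration_s * fps + 1` rows.
#' @export
simulate_cohort <- function(config) {
  if (!inherits(config, "sim_config"))
    stop_vt("'config' must be a sim_config object")
  n_frames <- as.integer(round(config$duration_s * config$fps)) + 1L
  with_seed(derive_seed(config$seed, "simulate"), {
    per_vial <- lapply(seq_len(config$n_vials), function(v)
      simulate_vial(config, v, n_frames))
  })
  out <- do.call(rbind, per_vial)
  rownames(out) <- NULL
  structure(out, class = c("gt_tracks", "data.frame"), sim_config = config)
}

simulate_vial <- function(cfg, vial_id, n_frames) {
  n <- cfg$flies_per_vial
  if (n == 0L) {
    return(data.frame(vial_id = integer(0), fly_id = integer(0),
                      frame = integer(0), t_s = numeric(0), x_mm = numeric(0),
                      y_mm = numeric(0), walking = logical(0)))
  }
  w <- cfg$tube_width_mm; L <- cfg$tube_length_mm
  sep <- cfg$min_separation_mm
  # initial positions (rejection-sampled for separation if requested)
  x <- runif(n, 0, w); y <- runif(n, 0, L)
  if (sep > 0) {
    if (sep * sep * n > 0.5 * w * L)
      stop_vt("min_separation_mm %.3g mm is too large for %d flies in a %g x %g mm tube",
              sep, n, w, L)
    for (tries in 1:10000) {
      d <- as.matrix(dist(cbind(x, y))); diag(d) <- Inf
      bad <- unique(which(d < sep, arr.ind = TRUE)[, 1L])
      if (!length(bad)) break
      x[bad] <- runif(length(bad), 0, w)
      y[bad] <- runif(length(bad), 0, L)
    }
    if (length(bad)) stop_vt("could not place %d flies at separation %.3g mm", n, sep)
  }
  p_occ <- if (cfg$p_start_walk + cfg$p_stop_walk > 0)
    cfg$p_start_walk / (cfg$p_start_walk + cfg$p_stop_walk) else 0
  walking <- runif(n) < p_occ
  speed <- draw_episode_speed(n, cfg$walk_speed_mean_mm_s, cfg$walk_speed_sd_mm_s)
  ang <- runif(n, 0, 2 * pi)
  hx <- cos(ang); hy <- sin(ang)
  step_drift <- cfg$geotaxis_drift_mm_s / cfg$fps
  h <- cfg$heading_persistence

  X <- matrix(0, n_frames, n); Y <- matrix(0, n_frames, n)
  S <- matrix(FALSE, n_frames, n)
  X[1L, ] <- x; Y[1L, ] <- y; S[1L, ] <- walking

  for (f in 2L:n_frames) {
    u <- runif(n)
    starts <- !walking & u < cfg$p_start_walk
    stops  <-  walking & u < cfg$p_stop_walk
    if (any(starts))
      speed[starts] <- draw_episode_speed(sum(starts), cfg$walk_speed_mean_mm_s,
                                          cfg$walk_speed_sd_mm_s)
    walking <- (walking | starts) & !stops
    mv <- which(walking)
    if (length(mv)) {
      fresh <- runif(length(mv), 0, 2 * pi)
      nhx <- h * hx[mv] + (1 - h) * cos(fresh)
      nhy <- h * hy[mv] + (1 - h) * sin(fresh)
      nrm <- sqrt(nhx^2 + nhy^2)
      deg <- nrm < 1e-12
      if (any(deg)) { nhx[deg] <- cos(fresh[deg]); nhy[deg] <- sin(fresh[deg]); nrm[deg] <- 1 }
      hx[mv] <- nhx / nrm; hy[mv] <- nhy / nrm
      step <- speed[mv] / cfg$fps
      for (k in seq_along(mv)) {
        i <- mv[k]
        others <- if (sep > 0) setdiff(seq_len(n), i) else integer(0)
        # on a blocked move the fly turns away (fresh headings) rather than
        # freezing, so crowded flies keep moving and separation still holds
        for (try in 1:8) {
          if (try > 1L) {
            a2 <- runif(1, 0, 2 * pi)
            hx[i] <- cos(a2); hy[i] <- sin(a2)
          }
          nx <- x[i] + hx[i] * step[k]
          ny <- y[i] + hy[i] * step[k] + step_drift
          # reflecting walls (flip the heading component that hit)
          while (nx < 0 || nx > w) {
            if (nx < 0) { nx <- -nx; hx[i] <- -hx[i] }
            else { nx <- 2 * w - nx; hx[i] <- -hx[i] }
          }
          while (ny < 0 || ny > L) {
            if (ny < 0) { ny <- -ny; hy[i] <- -hy[i] }
            else { ny <- 2 * L - ny; hy[i] <- -hy[i] }
          }
          if (!length(others) ||
              !any((nx - x[others])^2 + (ny - y[others])^2 < sep * sep)) {
            x[i] <- nx; y[i] <- ny
            break
          }
        }
      }
    }
    X[f, ] <- x; Y[f, ] <- y; S[f, ] <- walking
  }

  frames <- rep(0:(n_frames - 1L), times = n)
  data.frame(
    vial_id = vial_id,
    fly_id = rep(seq_len(n), each = n_frames),
    frame = frames,
    t_s = frames / cfg$fps,
    x_mm = as.vector(X),
    y_mm = as.vector(Y),
    walking = as.vector(S)
  )
}

# --- rendering ---------------------------------------------------------------

# Intensity of the unlit field around the tubes (8-bit).
FIELD_LEVEL <- 20
# Rows left blank above/below the tube strip in a rendered frame.
TUBE_MARGIN_PX <- 15L

#' Pixel layout of the vial rack in a rendered frame
#'
#' Computes, for each vial, the bright-strip pixel bounds and the isotropic
#' mm-per-pixel scale implied by the tube length spanning the strip height.
#'
#' @param config A [sim_config()] object.
#' @param width_px,height_px Frame dimensions in pixels.
#' @return Data frame with one row per vial: `vial_id`, `x_min_px`,
#'   `x_max_px`, `y_min_px`, `y_max_px`, `mm_per_px`.
#' @export
vial_layout <- function(config, width_px = 640L, height_px = 480L) {
  y_min <- TUBE_MARGIN_PX + 1L
  y_max <- height_px - TUBE_MARGIN_PX
  mm_per_px <- config$tube_length_mm / (y_max - y_min)
  half_w <- round(config$tube_width_mm / mm_per_px / 2)
  centers <- round(width_px * (seq_len(config$n_vials) - 0.5) / config$n_vials)
  out <- data.frame(
    vial_id = seq_len(config$n_vials),
    x_min_px = centers - half_w,
    x_max_px = centers + half_w,
    y_min_px = y_min,
    y_max_px = y_max,
    mm_per_px = mm_per_px
  )
  if (out$x_min_px[1L] < 1L || out$x_max_px[config$n_vials] > width_px ||
      (config$n_vials > 1L &&
       any(out$x_min_px[-1L] <= out$x_max_px[-config$n_vials])))
    stop_vt("vial strips do not fit in a %d px wide frame", width_px)
  out
}

#' Render ground-truth trajectories to camera frames
#'
#' Draws each vial as a bright vertical strip on a dark field and each fly
#' as a dark anti-aliased disc at its projected pixel position, then adds
#' clipped Gaussian pixel noise. The mm-to-pixel projection is the per-vial
#' calibration implied by the tube length spanning the strip height; discs
#' are clipped to their strip.
#'
#' @param tracks A `gt_tracks` data frame from [simulate_cohort()].
#' @param config The [sim_config()] used to generate `tracks`.
#' @param width_px,height_px Frame dimensions in pixels.
#' @return A [frame_sequence()] object.
#' @export
render_frames <- function(tracks, config, width_px = 640L, height_px = 480L) {
  if (!inherits(config, "sim_config"))
    stop_vt("'config' must be a sim_config object")
  if (nrow(tracks)) {
    if (any(tracks$x_mm < 0 | tracks$x_mm > config$tube_width_mm |
            tracks$y_mm < 0 | tracks$y_mm > config$tube_length_mm))
      stop_vt("track positions outside tube bounds")
    if (any(tracks$vial_id < 1L | tracks$vial_id > config$n_vials))
      stop_vt("track vial_id outside configured rack")
  }
  layout <- vial_layout(config, width_px, height_px)
  plate <- matrix(FIELD_LEVEL, nrow = height_px, ncol = width_px)
  for (v in seq_len(nrow(layout)))
    plate[layout$y_min_px[v]:layout$y_max_px[v],
          layout$x_min_px[v]:layout$x_max_px[v]] <- config$background_level

  n_frames <- as.integer(round(config$duration_s * config$fps)) + 1L
  by_frame <- if (nrow(tracks)) split(tracks, tracks$frame) else list()
  rad <- config$blob_radius_px
  depth <- config$background_level - config$fly_level

  frames <- with_seed(derive_seed(config$seed, "render"), {
    lapply(seq_len(n_frames) - 1L, function(f) {
      img <- plate
      rows <- by_frame[[as.character(f)]]
      if (!is.null(rows)) {
        for (k in seq_len(nrow(rows))) {
          v <- rows$vial_id[k]
          mmpp <- layout$mm_per_px[v]
          cc <- layout$x_min_px[v] + rows$x_mm[k] / mmpp
          rr <- layout$y_max_px[v] - rows$y_mm[k] / mmpp
          r0 <- max(floor(rr - rad), layout$y_min_px[v])
          r1 <- min(ceiling(rr + rad), layout$y_max_px[v])
          c0 <- max(floor(cc - rad), layout$x_min_px[v])
          c1 <- min(ceiling(cc + rad), layout$x_max_px[v])
          if (r0 > r1 || c0 > c1) next
          ri <- r0:r1; ci <- c0:c1
          d <- sqrt(outer((ri - rr)^2, (ci - cc)^2, `+`))
          cov <- pmin(pmax(rad + 0.5 - d, 0), 1)
          val <- config$background_level - cov * depth
          img[ri, ci] <- pmin(img[ri, ci], val)
        }
      }
      if (config$noise_sd > 0)
        img <- img + matrix(rnorm(length(img), 0, config$noise_sd),
                            nrow = height_px)
      matrix(as.integer(pmin(pmax(round(img), 0), 255)), nrow = height_px)
    })
  })

  frame_sequence(frames, fps = config$fps, source = "synthetic",
                 layout = layout, seed = config$seed)
}
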