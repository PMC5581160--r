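test_that("sim_config validates fields and names the offender", {
  expect_s3_class(sim_config(), "sim_config")
  expect_error(sim_config(p_start_walk = 1.2), "p_start_walk")
  expect_error(sim_config(fps = 0), "fps")
  expect_error(sim_config(walk_speed_mean_mm_s = -1), "walk_speed_mean_mm_s")
  expect_error(sim_config(fly_level = 210), "fly_level")
  expect_error(sim_config(noise_sd = NaN), "noise_sd")
})

test_that("simulation is deterministic and respects the pause state", {
  cfg <- sim_config(n_vials = 1, flies_per_vial = 4, duration_s = 2,
                    seed = 42)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$x_mm, b$x_mm)
  expect_identical(a$y_mm, b$y_mm)
  expect_identical(a$walking, b$walking)

  # p_start_walk = 0 puts the stationary distribution entirely on "paused":
  # no fly ever walks, so zero displacement
  frozen <- simulate_cohort(sim_config(n_vials = 1, flies_per_vial = 5,
                                       duration_s = 2, p_start_walk = 0,
                                       seed = 3))
  expect_false(any(frozen$walking))
  disp <- vapply(split(frozen, frozen$fly_id), function(d)
    sum(abs(diff(d$x_mm))) + sum(abs(diff(d$y_mm))), numeric(1))
  expect_equal(unname(disp), rep(0, 5))
})

test_that("track shape matches the recording geometry", {
  cfg <- sim_config(n_vials = 2, flies_per_vial = 3, duration_s = 1.5,
                    seed = 9)
  tr <- simulate_cohort(cfg)
  n_frames <- cfg$duration_s * cfg$fps + 1
  expect_equal(nrow(tr), 2 * 3 * n_frames)
  expect_true(all(tr$x_mm >= 0 & tr$x_mm <= cfg$tube_width_mm))
  expect_true(all(tr$y_mm >= 0 & tr$y_mm <= cfg$tube_length_mm))
  for (d in split(tr, interaction(tr$vial_id, tr$fly_id)))
    expect_equal(diff(d$t_s), rep(1 / cfg$fps, n_frames - 1))
})

test_that("realized walking speed matches the configured distribution", {
  # continuous walking, straight headings, no drift: each fly's realized
  # per-frame step speed equals its episode draw, so the cross-fly mean
  # estimates the (truncation-negligible) configured mean
  cfg <- sim_config(n_vials = 1, flies_per_vial = 100, duration_s = 2,
                    p_start_walk = 1, p_stop_walk = 0,
                    heading_persistence = 1, geotaxis_drift_mm_s = 0,
                    min_separation_mm = 0, seed = 101)
  tr <- simulate_cohort(cfg)
  per_fly <- vapply(split(tr, tr$fly_id), function(d)
    mean(sqrt(diff(d$x_mm)^2 + diff(d$y_mm)^2)) * cfg$fps, numeric(1))
  se <- stats::sd(per_fly) / sqrt(length(per_fly))
  expect_lt(abs(mean(per_fly) - cfg$walk_speed_mean_mm_s), 3 * se)
})

test_that("walk-state occupancy converges to the stationary value", {
  cfg <- sim_config(n_vials = 1, flies_per_vial = 100, duration_s = 30,
                    min_separation_mm = 0, seed = 5)
  tr <- simulate_cohort(cfg)
  p <- cfg$p_start_walk / (cfg$p_start_walk + cfg$p_stop_walk)
  # successive fly-frames are Markov-correlated with lag-1 correlation
  # r = 1 - p_start - p_stop; the binomial SE must use the effective sample
  # size, i.e. be inflated by sqrt((1+r)/(1-r))
  r <- 1 - cfg$p_start_walk - cfg$p_stop_walk
  se <- sqrt(p * (1 - p) / nrow(tr)) * sqrt((1 + r) / (1 - r))
  expect_lt(abs(mean(tr$walking) - p), 3 * se)
})

test_that("rendering is deterministic and validates bounds", {
  cfg <- sim_config(n_vials = 1, flies_per_vial = 2, duration_s = 0.2,
                    seed = 8)
  tr <- simulate_cohort(cfg)
  f1 <- render_frames(tr, cfg)
  f2 <- render_frames(tr, cfg)
  expect_identical(f1$frames, f2$frames)

  bad <- tr
  bad$y_mm[1] <- cfg$tube_length_mm + 1
  expect_error(render_frames(bad, cfg), "outside tube bounds")
})

test_that("empty and stationary renders look as constructed", {
  cfg <- sim_config(n_vials = 1, flies_per_vial = 0, duration_s = 0.1,
                    noise_sd = 0, seed = 2)
  fs <- render_frames(simulate_cohort(cfg), cfg)
  # zero flies, zero noise: constant images equal to the plate
  expect_true(all(vapply(fs$frames, identical, logical(1), fs$frames[[1]])))
  expect_setequal(unique(as.vector(fs$frames[[1]])),
                  c(20, cfg$background_level))

  one <- stationary_tracks(data.frame(x = 6.5, y = 40), cfg)
  fs1 <- render_frames(one, cfg)
  expect_identical(fs1$frames[[1]], fs1$frames[[2]])
  # darkest pixel inside the tube strip sits at the projected centroid
  # (the unlit field around the strip is darker still, so restrict to it)
  lay <- fs1$layout
  strip <- fs1$frames[[1]][lay$y_min_px:lay$y_max_px,
                           lay$x_min_px:lay$x_max_px]
  # the fully-covered disc core is a plateau of equally dark pixels, so
  # compare its centroid (not each extreme pixel) to the projection
  dark <- which(strip == min(strip), arr.ind = TRUE)
  exp_col <- 6.5 / lay$mm_per_px + 1
  exp_row <- (lay$y_max_px - lay$y_min_px + 1) - 40 / lay$mm_per_px
  expect_lt(abs(mean(dark[, 1]) - exp_row), 1)
  expect_lt(abs(mean(dark[, 2]) - exp_col), 1)
})

test_that("ten non-overlapping stationary flies render as ten components", {
  cfg <- sim_config(n_vials = 1, flies_per_vial = 10, duration_s = 0.1,
                    noise_sd = 0, seed = 4)
  pos <- data.frame(x = rep(c(4, 9), 5), y = seq(10, 66, length.out = 10))
  fs <- render_frames(stationary_tracks(pos, cfg), cfg)
  lay <- fs$layout
  strip <- fs$frames[[1]][lay$y_min_px:lay$y_max_px,
                          lay$x_min_px:lay$x_max_px]
  mask <- strip < cfg$background_level - 25
  expect_equal(flood_count(mask), 10)
})

test_that("projection round-trips within one pixel's mm equivalent", {
  cfg <- sim_config(n_vials = 4)
  lay <- vial_layout(cfg)
  expect_equal(nrow(lay), 4)
  expect_true(all(diff(lay$x_min_px) > 0))
  for (v in c(1, 3)) {
    x <- 7.2; y <- 33.3
    col <- lay$x_min_px[v] + x / lay$mm_per_px[v]
    row <- lay$y_max_px[v] - y / lay$mm_per_px[v]
    # a renderer quantizes to whole pixels; the inverse projection of the
    # rounded pixel must land within one pixel's mm equivalent
    x_back <- (round(col) - lay$x_min_px[v]) * lay$mm_per_px[v]
    y_back <- (lay$y_max_px[v] - round(row)) * lay$mm_per_px[v]
    expect_lt(abs(x_back - x), lay$mm_per_px[v])
    expect_lt(abs(y_back - y), lay$mm_per_px[v])
  }
})

test_that("separation constraint holds throughout a crowded simulation", {
  cfg <- sim_config(n_vials = 1, flies_per_vial = 8, duration_s = 2,
                    min_separation_mm = 3, seed = 12)
  tr <- simulate_cohort(cfg)
  min_d <- min(vapply(split(tr, tr$frame), function(d) {
    dd <- stats::dist(cbind(d$x_mm, d$y_mm))
    min(dd)
  }, numeric(1)))
  expect_gte(min_d, 3)
})
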