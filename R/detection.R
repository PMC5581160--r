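# Fly detector: background estimation, vial ROI segmentation, millimetre
# calibration, per-frame blob detection and per-recording fly counting.
# Polarity is fixed dark-on-bright (backlit tubes): signal = background - frame.

#' Estimate the static background of a recording
#'
#' Per-pixel temporal median over up to `max_samples` evenly spaced frames.
#' The median is robust to moving flies, so no fly-free reference shot is
#' needed: any pixel a fly occupies in fewer than half of the sampled
#' frames recovers the empty plate.
#'
#' @param fs A [frame_sequence()] with at least 2 frames.
#' @param max_samples Maximum number of frames entering the median.
#' @return Numeric matrix with the dimensions of one frame.
#' @export
estimate_background <- function(fs, max_samples = 25L) {
  if (!inherits(fs, "frame_sequence")) stop_vt("'fs' must be a frame_sequence")
  n <- length(fs$frames)
  if (n < 2L) stop_vt("background estimation needs at least 2 frames (got %d)", n)
  max_samples <- check_count(max_samples, "max_samples", 2L)
  idx <- unique(round(seq(1L, n, length.out = min(max_samples, n))))
  stack <- vapply(fs$frames[idx], as.numeric,
                  numeric(fs$width_px * fs$height_px))
  matrix(row_medians(stack), nrow = fs$height_px)
}

#' Segment vial regions from a background image
#'
#' Vials appear as bright vertical strips. Columns whose mean intensity
#' exceeds the global Otsu split of the background are grouped into
#' contiguous bands; the `n_expected` widest bands become regions, ordered
#' left to right. Each band's vertical extent is found by thresholding the
#' band's row profile with the same split.
#'
#' @param background Intensity matrix from [estimate_background()].
#' @param n_expected Number of vials to find.
#' @return Data frame of uncalibrated regions: `vial_id`, `x_min_px`,
#'   `x_max_px`, `y_min_px`, `y_max_px`, `mm_per_px` (`NA` until
#'   [calibrate()]).
#' @export
segment_vials <- function(background, n_expected) {
  n_expected <- check_count(n_expected, "n_expected", 1L)
  thr <- otsu_threshold(as.numeric(background))
  col_on <- colMeans(background) > thr
  r <- rle(col_on)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  bands <- data.frame(start = starts[r$values], end = ends[r$values],
                      width = r$lengths[r$values])
  if (nrow(bands) < n_expected)
    stop_vt("expected %d vial strips but found %d", n_expected, nrow(bands))
  bands <- bands[order(-bands$width)[seq_len(n_expected)], ]
  bands <- bands[order(bands$start), ]
  out <- lapply(seq_len(n_expected), function(i) {
    cols <- bands$start[i]:bands$end[i]
    row_on <- rowMeans(background[, cols, drop = FALSE]) > thr
    if (!any(row_on)) stop_vt("vial strip %d has no rows above threshold", i)
    data.frame(vial_id = i, x_min_px = bands$start[i], x_max_px = bands$end[i],
               y_min_px = min(which(row_on)), y_max_px = max(which(row_on)),
               mm_per_px = NA_real_)
  })
  do.call(rbind, out)
}

#' Calibrate a vial region to millimetres
#'
#' Sets the isotropic scale `mm_per_px = tube_length_mm / (y_max_px -
#' y_min_px)`, i.e. the known tube length spans the strip height. The tube
#' width is used as a consistency check: a discrepancy beyond 10% of the
#' implied strip width raises a warning (not an error), since perspective
#' and strip-edge effects distort width more than height.
#'
#' @param regions Region data frame from [segment_vials()] (one or more rows).
#' @param tube_length_mm Physical tube length in mm.
#' @param tube_width_mm Optional physical tube width in mm for the check.
#' @return The regions with `mm_per_px` filled in.
#' @export
calibrate <- function(regions, tube_length_mm, tube_width_mm = NULL) {
  check_scalar_number(tube_length_mm, "tube_length_mm", 0, strict_min = TRUE)
  h <- regions$y_max_px - regions$y_min_px
  if (any(h <= 0)) stop_vt("zero-height vial region cannot be calibrated")
  regions$mm_per_px <- tube_length_mm / h
  if (!is.null(tube_width_mm)) {
    w_px <- regions$x_max_px - regions$x_min_px
    w_mm <- w_px * regions$mm_per_px
    off <- abs(w_mm - tube_width_mm) / tube_width_mm
    if (any(off > 0.10))
      warning(sprintf(
        "vial width check: measured %.1f mm vs expected %.1f mm (>10%% off)",
        w_mm[which.max(off)], tube_width_mm), call. = FALSE)
  }
  regions
}

#' Detect flies in one frame
#'
#' Within each calibrated region, pixels with `background - frame >
#' contrast_min` form a mask; 8-connected components with area in
#' `[area_min, area_max]` become detections. The centroid is the
#' contrast-weighted mean pixel position, converted to vial millimetre
#' coordinates with `cy_mm` measured upward from the tube bottom
#' (`y_max_px`). Merged blobs from occluding flies stay single detections.
#'
#' @param frame Intensity matrix.
#' @param background Matrix from [estimate_background()].
#' @param regions Calibrated region data frame (see [calibrate()]).
#' @param params List with `contrast_min`, `area_min`, `area_max`; defaults
#'   from [default_config()].
#' @return Data frame: `frame` (`NA`; filled by callers), `vial_id`,
#'   `cx_mm`, `cy_mm`, `area_px`, `peak_contrast`.
#' @export
detect_flies <- function(frame, background, regions, params = list()) {
  defaults <- default_config()
  p <- utils::modifyList(defaults[c("contrast_min", "area_min", "area_max")],
                         params)
  if (anyNA(regions$mm_per_px))
    stop_vt("regions must be calibrated (mm_per_px is NA); call calibrate()")
  diffm <- background - frame
  out <- list()
  for (i in seq_len(nrow(regions))) {
    rg <- regions[i, ]
    sub <- diffm[rg$y_min_px:rg$y_max_px, rg$x_min_px:rg$x_max_px, drop = FALSE]
    px <- which(sub > p$contrast_min, arr.ind = TRUE)
    if (!nrow(px)) next
    lab <- label_components(px)
    w <- sub[px]
    for (l in seq_len(max(lab))) {
      sel <- lab == l
      area <- sum(sel)
      if (area < p$area_min || area > p$area_max) next
      wk <- w[sel]
      r_c <- sum(px[sel, 1L] * wk) / sum(wk) + rg$y_min_px - 1L
      c_c <- sum(px[sel, 2L] * wk) / sum(wk) + rg$x_min_px - 1L
      out[[length(out) + 1L]] <- data.frame(
        frame = NA_integer_, vial_id = rg$vial_id,
        cx_mm = (c_c - rg$x_min_px) * rg$mm_per_px,
        cy_mm = (rg$y_max_px - r_c) * rg$mm_per_px,
        area_px = area, peak_contrast = max(wk))
    }
  }
  if (!length(out))
    return(data.frame(frame = integer(0), vial_id = integer(0),
                      cx_mm = numeric(0), cy_mm = numeric(0),
                      area_px = integer(0), peak_contrast = numeric(0)))
  do.call(rbind, out)
}

#' Detect flies across a whole recording
#'
#' Convenience wrapper running [estimate_background()], [segment_vials()],
#' [calibrate()] and [detect_flies()] on every frame.
#'
#' @param fs A [frame_sequence()].
#' @param n_vials Number of vials to segment.
#' @param config Configuration list (see [default_config()]).
#' @return List with `detections` (data frame over all frames, `frame`
#'   0-based), `regions` (calibrated), `background`.
#' @export
detect_recording <- function(fs, n_vials = NULL, config = default_config()) {
  if (is.null(n_vials)) n_vials <- config$n_vials
  background <- estimate_background(fs, config$max_samples)
  regions <- segment_vials(background, n_vials)
  regions <- calibrate(regions, config$tube_length_mm, config$tube_width_mm)
  params <- config[c("contrast_min", "area_min", "area_max")]
  per_frame <- lapply(seq_along(fs$frames), function(i) {
    d <- detect_flies(fs$frames[[i]], background, regions, params)
    if (nrow(d)) d$frame <- i - 1L
    d
  })
  detections <- do.call(rbind, per_frame)
  rownames(detections) <- NULL
  list(detections = detections, regions = regions, background = background)
}

#' Count the flies in a vial over a recording
#'
#' The modal per-frame detection count, with ties broken toward the larger
#' count: occlusion merges blobs, so undercounts are more likely than
#' overcounts. Frames with no detection for the vial count as zero.
#'
#' @param detections Detection data frame spanning the recording.
#' @param vial_id Vial to count.
#' @param n_frames Total number of frames in the recording.
#' @return Integer fly count (0 for an empty vial).
#' @export
count_flies <- function(detections, vial_id, n_frames) {
  n_frames <- check_count(n_frames, "n_frames", 1L)
  if (n_frames < 30L)
    warning("fly counting is intended for recordings of >= 30 frames",
            call. = FALSE)
  d <- detections[detections$vial_id == vial_id, , drop = FALSE]
  if (!nrow(d)) return(0L)
  per_frame <- tabulate(d$frame + 1L, nbins = n_frames)
  counts <- table(per_frame)
  vals <- as.integer(names(counts))
  best <- max(vals[counts == max(counts)])
  best
}
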