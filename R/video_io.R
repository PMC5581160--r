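# Frame-sequence and table I/O. PNG frame directories carry a JSON sidecar
# with acquisition metadata (fps is mandatory for kinematics); trajectory
# and detection tables are plain CSV (comma separator, '.' decimal, UTF-8,
# mandatory header) to avoid locale drift.

#' Construct a frame sequence
#'
#' An ordered set of 8-bit grayscale frames with acquisition metadata.
#'
#' @param frames List of integer matrices (rows = image rows, top-left
#'   origin), all with identical dimensions, values in 0..255.
#' @param fps Frame rate in frames per second.
#' @param source Provenance string.
#' @param layout Optional vial layout data frame (see [vial_layout()]).
#' @param seed Optional integer seed recorded for provenance.
#' @return An object of class `frame_sequence`.
#' @export
frame_sequence <- function(frames, fps, source = "unknown", layout = NULL,
                           seed = NULL) {
  if (!is.list(frames) || !length(frames))
    stop_vt("'frames' must be a non-empty list of matrices")
  dims <- vapply(frames, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop_vt("all frames must share identical dimensions")
  check_scalar_number(fps, "fps", 0, strict_min = TRUE)
  structure(
    list(frames = frames, fps = fps,
         width_px = dims[2, 1], height_px = dims[1, 1],
         source = source, layout = layout, seed = seed),
    class = "frame_sequence")
}

#' @export
print.frame_sequence <- function(x, ...) {
  cat(sprintf("<frame_sequence> %d frames, %d x %d px @ %.3g fps (%s)\n",
              length(x$frames), x$width_px, x$height_px, x$fps, x$source))
  invisible(x)
}

#' Write a frame sequence as a PNG directory
#'
#' Writes zero-padded grayscale PNG frames (`frame_000000.png`, ...) plus a
#' `sequence.json` sidecar holding fps, pixel dimensions, frame count,
#' source, seed and (if present) the vial layout.
#'
#' @param fs A [frame_sequence()].
#' @param path Output directory (created if missing).
#' @return `path`, invisibly.
#' @export
write_frame_sequence <- function(fs, path) {
  if (!inherits(fs, "frame_sequence")) stop_vt("'fs' must be a frame_sequence")
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(fs$frames)) {
    png::writePNG(fs$frames[[i]] / 255,
                  file.path(path, sprintf("frame_%06d.png", i - 1L)))
  }
  meta <- list(fps = fs$fps, width_px = fs$width_px, height_px = fs$height_px,
               n_frames = length(fs$frames), source = fs$source)
  if (!is.null(fs$seed)) meta$seed <- fs$seed
  if (!is.null(fs$layout)) meta$layout <- fs$layout
  jsonlite::write_json(meta, file.path(path, "sequence.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  invisible(path)
}

rgb_to_gray <- function(a) {
  # Rec. 601 luminance, the video convention
  0.299 * a[, , 1] + 0.587 * a[, , 2] + 0.114 * a[, , 3]
}

#' Read a frame sequence
#'
#' Reads a directory of lexicographically ordered PNG frames with a
#' `sequence.json` sidecar. Colour frames are converted to grayscale by
#' Rec. 601 luminance. The frame rate comes from the sidecar unless
#' `fps_override` is given. Video containers (AVI/MP4) are not supported in
#' this build; extract frames to PNG first.
#'
#' @param path Directory of PNG frames.
#' @param fps_override Optional frame rate overriding the sidecar.
#' @return A [frame_sequence()].
#' @export
read_frame_sequence <- function(path, fps_override = NULL) {
  if (!file.exists(path)) stop_vt("frame source not found: %s", path)
  if (!dir.exists(path)) {
    ext <- tolower(tools::file_ext(path))
    if (ext %in% c("avi", "mp4", "mov", "mkv"))
      stop_vt(paste0("video containers (.%s) are not supported in this build;",
                     " extract frames to a PNG directory first"), ext)
    stop_vt("'path' must be a directory of PNG frames: %s", path)
  }
  files <- sort(list.files(path, pattern = "\\.png$", full.names = TRUE))
  if (!length(files)) stop_vt("no PNG frames found in %s", path)
  sidecar <- file.path(path, "sequence.json")
  meta <- if (file.exists(sidecar))
    jsonlite::read_json(sidecar, simplifyVector = TRUE) else NULL
  fps <- if (!is.null(fps_override)) fps_override else meta$fps
  if (is.null(fps))
    stop_vt("no sequence.json sidecar with fps in %s and no fps_override given", path)
  frames <- lapply(files, function(f) {
    a <- png::readPNG(f)
    if (length(dim(a)) == 3L) a <- rgb_to_gray(a)
    matrix(as.integer(round(a * 255)), nrow = nrow(a))
  })
  dims <- vapply(frames, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop_vt("frames in %s have inconsistent dimensions", path)
  layout <- if (!is.null(meta$layout)) as.data.frame(meta$layout) else NULL
  frame_sequence(frames, fps = fps,
                 source = if (!is.null(meta$source)) meta$source else path,
                 layout = layout, seed = meta$seed)
}

# --- CSV tables --------------------------------------------------------------

read_csv_checked <- function(path, expected, what, numeric_cols) {
  if (!file.exists(path)) stop_vt("%s file not found: %s", what, path)
  header <- strsplit(readLines(path, n = 1L), ",", fixed = TRUE)[[1]]
  missing <- setdiff(expected, header)
  if (length(missing))
    stop_vt("%s file %s: missing column(s) %s", what, path,
            paste(missing, collapse = ", "))
  df <- utils::read.csv(path, colClasses = "character",
                        check.names = FALSE)[expected]
  for (col in numeric_cols) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) & !is.na(df[[col]]) & nzchar(df[[col]]))
    if (length(bad))
      stop_vt("%s file %s: non-numeric value '%s' in column '%s' at line %d",
              what, path, df[[col]][bad[1]], col, bad[1] + 1L)
    if (anyNA(v)) stop_vt("%s file %s: missing value in column '%s'", what, path, col)
    df[[col]] <- v
  }
  df
}

#' Write / read fly tracks
#'
#' Tracks are stored as CSV with header
#' `vial_id,fly_id,frame,t_s,x_mm,y_mm,interpolated`; coordinates are
#' written with enough precision that a write/read round trip reproduces
#' them to at least 6 decimal places. An empty track table yields a
#' header-only file.
#'
#' @param tracks Track data frame (see [build_tracks()]).
#' @param path CSV file path.
#' @return `write_tracks()` returns `path` invisibly; `read_tracks()`
#'   returns the track data frame.
#' @export
write_tracks <- function(tracks, path) {
  cols <- c("vial_id", "fly_id", "frame", "t_s", "x_mm", "y_mm", "interpolated")
  missing <- setdiff(cols, names(tracks))
  if (length(missing))
    stop_vt("tracks are missing column(s): %s", paste(missing, collapse = ", "))
  df <- as.data.frame(tracks)[cols]
  df$interpolated <- as.integer(df$interpolated)
  utils::write.csv(format(df, digits = 15, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_tracks
#' @export
read_tracks <- function(path) {
  cols <- c("vial_id", "fly_id", "frame", "t_s", "x_mm", "y_mm", "interpolated")
  df <- read_csv_checked(path, cols, "tracks", cols)
  df$vial_id <- as.integer(df$vial_id)
  df$fly_id <- as.integer(df$fly_id)
  df$frame <- as.integer(df$frame)
  df$interpolated <- df$interpolated != 0
  df
}

#' Write / read ground-truth trajectories
#'
#' CSV with header `vial_id,fly_id,frame,t_s,x_mm,y_mm,walking`.
#'
#' @param tracks A `gt_tracks` data frame from [simulate_cohort()].
#' @param path CSV file path.
#' @return `write_ground_truth()` returns `path` invisibly;
#'   `read_ground_truth()` returns the data frame.
#' @export
write_ground_truth <- function(tracks, path) {
  cols <- c("vial_id", "fly_id", "frame", "t_s", "x_mm", "y_mm", "walking")
  df <- as.data.frame(tracks)[cols]
  df$walking <- as.integer(df$walking)
  utils::write.csv(format(df, digits = 15, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  cols <- c("vial_id", "fly_id", "frame", "t_s", "x_mm", "y_mm", "walking")
  df <- read_csv_checked(path, cols, "ground truth", cols)
  df$vial_id <- as.integer(df$vial_id)
  df$fly_id <- as.integer(df$fly_id)
  df$frame <- as.integer(df$frame)
  df$walking <- df$walking != 0
  structure(df, class = c("gt_tracks", "data.frame"))
}

#' Write / read per-frame detections
#'
#' CSV with header `frame,vial_id,cx_mm,cy_mm,area_px,peak_contrast`.
#'
#' @param detections Detection data frame (see [detect_flies()]).
#' @param path CSV file path.
#' @return `write_detections()` returns `path` invisibly;
#'   `read_detections()` returns the data frame.
#' @export
write_detections <- function(detections, path) {
  cols <- c("frame", "vial_id", "cx_mm", "cy_mm", "area_px", "peak_contrast")
  df <- as.data.frame(detections)[cols]
  utils::write.csv(format(df, digits = 15, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_detections
#' @export
read_detections <- function(path) {
  cols <- c("frame", "vial_id", "cx_mm", "cy_mm", "area_px", "peak_contrast")
  df <- read_csv_checked(path, cols, "detections", cols)
  df$frame <- as.integer(df$frame)
  df$vial_id <- as.integer(df$vial_id)
  df$area_px <- as.integer(df$area_px)
  df
}
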