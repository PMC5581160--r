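#' Default analysis configuration
#'
#' Central registry of every tunable parameter of the detection, tracking
#' and kinematics stages, with the package defaults. Thresholds follow the
#' assay conventions: progressive walking requires a speed of at least
#' `walk_threshold_mm_s` (2 mm/s), and a fly counts as "in motion" only
#' strictly above `motion_cutoff_mm_s` (2.5 mm/s).
#'
#' @return Named list of configuration values.
#' @export
default_config <- function() {
  list(
    fps                = 30,
    n_vials            = 4L,
    tube_length_mm     = 75,
    tube_width_mm      = 13,
    # kinematics
    walk_threshold_mm_s = 2.0,
    motion_cutoff_mm_s  = 2.5,
    window_frames       = 5L,
    min_episode_s       = 0.2,
    # detection
    contrast_min = 25,
    area_min     = 4L,
    area_max     = 400L,
    max_samples  = 25L,
    # tracking
    gate_mm_per_s    = 60,
    max_gap_frames   = 3L,
    min_track_frames = 15L
  )
}

validate_config <- function(cfg) {
  check_scalar_number(cfg$fps, "fps", 0, strict_min = TRUE)
  cfg$n_vials <- check_count(cfg$n_vials, "n_vials", 1L)
  check_scalar_number(cfg$tube_length_mm, "tube_length_mm", 0, strict_min = TRUE)
  check_scalar_number(cfg$tube_width_mm, "tube_width_mm", 0, strict_min = TRUE)
  check_scalar_number(cfg$walk_threshold_mm_s, "walk_threshold_mm_s", 0)
  check_scalar_number(cfg$motion_cutoff_mm_s, "motion_cutoff_mm_s", 0)
  cfg$window_frames <- check_count(cfg$window_frames, "window_frames", 1L)
  if (cfg$window_frames %% 2L == 0L)
    stop_vt("'window_frames' must be odd (got %d)", cfg$window_frames)
  check_scalar_number(cfg$min_episode_s, "min_episode_s", 0)
  check_scalar_number(cfg$contrast_min, "contrast_min", 0)
  cfg$area_min <- check_count(cfg$area_min, "area_min", 1L)
  cfg$area_max <- check_count(cfg$area_max, "area_max", cfg$area_min)
  cfg$max_samples <- check_count(cfg$max_samples, "max_samples", 2L)
  check_scalar_number(cfg$gate_mm_per_s, "gate_mm_per_s", 0, strict_min = TRUE)
  cfg$max_gap_frames <- check_count(cfg$max_gap_frames, "max_gap_frames", 0L)
  cfg$min_track_frames <- check_count(cfg$min_track_frames, "min_track_frames", 1L)
  cfg
}

#' Load and validate a configuration file
#'
#' Reads a YAML (`.yaml`/`.yml`) or JSON (`.json`) configuration file,
#' fills missing keys with [default_config()] values and validates every
#' entry. Unknown keys are rejected so that a typo cannot silently fall
#' back to a default. An empty file yields the full default configuration.
#'
#' @param path Path to a YAML or JSON file.
#' @return Validated named list of configuration values.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop_vt("config file not found: %s", path)
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else if (ext == "json") {
    if (file.info(path)$size == 0) NULL
    else jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    stop_vt("unsupported config format '%s' (use .yaml, .yml or .json)", ext)
  }
  if (is.null(raw)) raw <- list()
  if (!is.list(raw)) stop_vt("config file must contain a mapping: %s", path)
  cfg <- default_config()
  unknown <- setdiff(names(raw), c(names(cfg), "simulation"))
  if (length(unknown))
    stop_vt("unknown config key(s): %s", paste(unknown, collapse = ", "))
  for (k in intersect(names(raw), names(cfg))) cfg[[k]] <- raw[[k]]
  cfg <- validate_config(cfg)
  if (!is.null(raw$simulation)) {
    if (!is.list(raw$simulation))
      stop_vt("'simulation' must be a mapping of simulator parameters")
    cfg$simulation <- do.call(sim_config, raw$simulation)
  }
  cfg
}
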