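#' Tracking and analysis configuration
#'
#' Builds the flat configuration list consumed by every stage of the
#' pipeline. All thresholds operate on 8-bit channel values (0-255);
#' geometric thresholds expressed as fractions are size-invariant and are
#' resolved against the animal measured in each frame.
#'
#' @param frame_rate_hz Acquisition frame rate in Hz.
#' @param px_per_cm Spatial calibration, pixels per centimetre.
#' @param bg_tolerance Symmetric per-channel range around the per-pixel
#'   median within which a pixel is considered background.
#' @param body_min,body_max Intensity (grayscale) or length-3 RGB bounds
#'   classifying a non-background pixel as body.
#' @param footprint_min,footprint_max Intensity or RGB bounds classifying a
#'   non-background pixel as footprint; the footprint rule has precedence
#'   over the body rule.
#' @param tail_thickness_frac Tail thickness threshold as a fraction of the
#'   maximum body width.
#' @param head_distance_frac Head extent as a fraction of body length.
#' @param footprint_close_px Radius (pixels) of the morphological closing
#'   applied to the footprint mask before blob labelling; bridges
#'   sub-threshold gaps between the pad and toes of one paw so a footprint
#'   is a single blob. 0 disables.
#' @param min_blob_area Minimum footprint blob area in pixels.
#' @param min_body_area Minimum body component area in pixels.
#' @param max_link_dist_px Maximum centroid distance for frame-to-frame
#'   blob linking.
#' @param max_gap_frames Maximum number of consecutive missing frames
#'   bridged inside one stance event.
#' @param max_stance_drift_px Maximum per-frame centroid drift of a
#'   floor-anchored footprint; also bounds linking across detection gaps.
#' @param min_stance_frames Minimum stance duration in frames.
#' @param fore_hind_split Longitudinal body-frame coordinate (body lengths,
#'   positive anterior) separating fore from hind placements.
#' @param fore_hind_dead_zone Half-width of the ambiguity band around
#'   `fore_hind_split`, in body lengths.
#' @param speed_smooth_win Centred moving-average window (frames) for
#'   instantaneous speed.
#' @param linearity_smooth_win Centred moving-average window (frames) for
#'   the stance and body linearity indexes.
#'
#' @return A named list of class `gait_config`.
#' @export
gait_config <- function(frame_rate_hz = 250,
                        px_per_cm = 8,
                        bg_tolerance = 12,
                        body_min = 70, body_max = 169,
                        footprint_min = 170, footprint_max = 255,
                        tail_thickness_frac = 0.25,
                        head_distance_frac = 0.25,
                        footprint_close_px = 1,
                        min_blob_area = 4,
                        min_body_area = 200,
                        max_link_dist_px = 20,
                        max_gap_frames = 2,
                        max_stance_drift_px = 3,
                        min_stance_frames = 3,
                        fore_hind_split = 0,
                        fore_hind_dead_zone = 0.02,
                        speed_smooth_win = 5,
                        linearity_smooth_win = 15) {
  cfg <- list(
    frame_rate_hz = frame_rate_hz, px_per_cm = px_per_cm,
    bg_tolerance = bg_tolerance,
    body_min = body_min, body_max = body_max,
    footprint_min = footprint_min, footprint_max = footprint_max,
    tail_thickness_frac = tail_thickness_frac,
    head_distance_frac = head_distance_frac,
    footprint_close_px = footprint_close_px,
    min_blob_area = min_blob_area, min_body_area = min_body_area,
    max_link_dist_px = max_link_dist_px, max_gap_frames = max_gap_frames,
    max_stance_drift_px = max_stance_drift_px,
    min_stance_frames = min_stance_frames,
    fore_hind_split = fore_hind_split,
    fore_hind_dead_zone = fore_hind_dead_zone,
    speed_smooth_win = speed_smooth_win,
    linearity_smooth_win = linearity_smooth_win
  )
  validate_gait_config(cfg)
  structure(cfg, class = "gait_config")
}

validate_gait_config <- function(cfg) {
  stopifnot(cfg$frame_rate_hz > 0, cfg$px_per_cm > 0)
  for (k in c("bg_tolerance", "body_min", "body_max",
              "footprint_min", "footprint_max")) {
    v <- cfg[[k]]
    if (any(v < 0) || any(v > 255)) {
      stop("config threshold '", k, "' outside [0, 255]", call. = FALSE)
    }
  }
  stopifnot(cfg$tail_thickness_frac > 0, cfg$head_distance_frac > 0,
            cfg$min_blob_area >= 1, cfg$min_body_area >= 1,
            cfg$max_gap_frames >= 0, cfg$min_stance_frames >= 1)
  invisible(cfg)
}

#' Read a configuration file
#'
#' Reads a flat YAML-style key-value file. Keys absent from the file keep
#' their [gait_config()] defaults; `frame_rate_hz` and `px_per_cm` are
#' mandatory (they are never inferred from the frames).
#'
#' @param path Path to the YAML configuration file.
#' @return A `gait_config` list.
#' @export
read_gait_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  for (k in c("frame_rate_hz", "px_per_cm")) {
    if (is.null(raw[[k]])) stop("missing config key: ", k, call. = FALSE)
  }
  known <- names(formals(gait_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    warning("ignoring unknown config keys: ", paste(unknown, collapse = ", "))
    raw <- raw[intersect(names(raw), known)]
  }
  do.call(gait_config, raw)
}

#' Write a configuration file
#'
#' @param cfg A `gait_config` list.
#' @param path Destination file.
#' @return `path`, invisibly.
#' @export
write_gait_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}
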