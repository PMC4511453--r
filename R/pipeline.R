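#' Track body and footprints through a frame sequence
#'
#' Runs the full segmentation and tracking front end: a per-pixel median
#' background over animal-free observations (frames where a pixel matches
#' the body or footprint colour rule are excluded via
#' [candidate_animal_mask()]), per-frame pixel classification, body-pose
#' decomposition, footprint blob extraction, blob linking into stance
#' events and leg identification.
#'
#' The background median is computed over an evenly spaced subsample of
#' at most `bg_frames` frames; with a moving animal this loses nothing
#' (each pixel is background in almost all frames) and bounds memory.
#'
#' @param frames List of `gait_frame` objects, or a path accepted by
#'   [read_frames()].
#' @param cfg A [gait_config()] list.
#' @param out_dir Optional directory for CSV outputs (`poses.csv`,
#'   `events.csv`, `footprints.csv`).
#' @param overlays Write per-frame debug overlay PNGs (body contour and
#'   footprint pixels) into `out_dir/overlays`.
#' @param bg_frames Maximum number of frames used for the background
#'   median.
#' @return A list of class `gait_track`: `poses`, `blobs`, `events`,
#'   `background`, `heatmap` (per-pixel maximum footprint brightness),
#'   `body_path`, `config`, `n_frames`.
#' @export
run_track <- function(frames, cfg, out_dir = NULL, overlays = FALSE,
                      bg_frames = 75) {
  validate_gait_config(cfg)
  if (is.character(frames)) frames <- read_frames(frames, cfg$frame_rate_hz)
  n <- length(frames)
  if (!n) stop("no frames to track", call. = FALSE)

  sub <- unique(round(seq(1, n, length.out = min(n, bg_frames))))
  excl <- lapply(frames[sub], candidate_animal_mask, cfg = cfg)
  bg <- build_background(frames[sub], exclusion_masks = excl,
                         tolerance = cfg$bg_tolerance)

  poses <- vector("list", n)
  blobs <- vector("list", n)
  heat <- matrix(0, nrow(bg$median), ncol(bg$median))
  prev_window <- NULL
  if (overlays && !is.null(out_dir)) {
    dir.create(file.path(out_dir, "overlays"), recursive = TRUE,
               showWarnings = FALSE)
  }
  for (i in seq_len(n)) {
    f <- frames[[i]]
    masks <- classify_pixels(f, bg, cfg)
    pose <- decompose_body(masks, cfg, frame_index = f$index,
                           prev = prev_window)
    poses[[i]] <- pose
    prev_window <- dplyr::bind_rows(poses[max(1, i - 5):i])
    fb <- extract_footprints(masks, f, cfg)
    blobs[[i]] <- fb
    if (any(masks$footprint)) {
      br <- frame_brightness(f)
      sel <- masks$footprint & br > heat
      heat[sel] <- br[sel]
    }
    if (overlays && !is.null(out_dir)) {
      write_overlay(f, masks, file.path(out_dir, "overlays",
                                        sprintf("overlay_%06d.png", f$index)))
    }
  }
  poses <- dplyr::bind_rows(poses)
  blobs <- dplyr::bind_rows(blobs)
  events <- link_blobs(blobs, cfg)
  events <- assign_leg_identity(events, poses, cfg)
  track <- structure(list(
    poses = poses, blobs = blobs, events = events, background = bg,
    heatmap = heat,
    body_path = poses[poses$tracked, c("frame", "center_x", "center_y")],
    config = cfg, n_frames = n
  ), class = "gait_track")
  if (!is.null(out_dir)) write_track(track, out_dir)
  track
}

write_overlay <- function(frame, masks, path) {
  br <- frame_brightness(frame) / 255
  arr <- array(br, c(dim(br), 3L))
  contour <- masks$body & !(EBImage::erode(masks$body + 0,
                                           EBImage::makeBrush(3, "box")) > 0)
  arr[, , 1][contour] <- 1; arr[, , 2][contour] <- 0; arr[, , 3][contour] <- 0
  arr[, , 2][masks$footprint] <- 1
  png::writePNG(arr, path)
}

#' Flatten stance events for CSV export
#'
#' @param events Nested event tibble.
#' @return One row per event with scalar columns only.
#' @export
events_table <- function(events) {
  events[, c("event_id", "leg", "ambiguous_leg", "onset", "offset",
             "mean_x", "mean_y", "peak_brightness")]
}

#' Per-frame footprint table of all events
#'
#' @param events Nested event tibble.
#' @return Tibble `event_id`, `leg`, `frame`, `x`, `y`, `area_px`,
#'   `brightness_sum`.
#' @export
footprints_table <- function(events) {
  if (!nrow(events)) {
    return(tibble::tibble(event_id = integer(), leg = character(),
                          frame = numeric(), x = numeric(), y = numeric(),
                          area_px = numeric(), brightness_sum = numeric()))
  }
  purrr::map_dfr(seq_len(nrow(events)), function(i) {
    tibble::tibble(event_id = events$event_id[i], leg = events$leg[i],
                   frame = events$frames[[i]], x = events$xs[[i]],
                   y = events$ys[[i]],
                   area_px = as.numeric(events$areas[[i]]),
                   brightness_sum = events$brightness[[i]])
  })
}

write_track <- function(track, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_table(track$poses, file.path(out_dir, "poses.csv"))
  write_table(events_table(track$events), file.path(out_dir, "events.csv"))
  write_table(footprints_table(track$events),
              file.path(out_dir, "footprints.csv"))
  invisible(out_dir)
}

# CSV writer with fixed 6-significant-digit float formatting so that
# re-running a stage on unchanged inputs is byte-identical
write_table <- function(df, path) {
  num <- vapply(df, is.double, logical(1))
  df[num] <- lapply(df[num], signif, digits = 6)
  readr::write_csv(df, path, progress = FALSE)
  invisible(path)
}

#' Rebuild a track object from `run_track` CSV outputs
#'
#' @param dir Directory containing `poses.csv`, `events.csv`,
#'   `footprints.csv`.
#' @param cfg The [gait_config()] used for tracking.
#' @return A `gait_track` (without background model and heat map).
#' @export
read_track <- function(dir, cfg) {
  poses <- readr::read_csv(file.path(dir, "poses.csv"), show_col_types = FALSE)
  ev <- readr::read_csv(file.path(dir, "events.csv"), show_col_types = FALSE)
  fp <- readr::read_csv(file.path(dir, "footprints.csv"), show_col_types = FALSE)
  events <- ev
  events$frames <- purrr::map(ev$event_id, ~fp$frame[fp$event_id == .x])
  events$xs <- purrr::map(ev$event_id, ~fp$x[fp$event_id == .x])
  events$ys <- purrr::map(ev$event_id, ~fp$y[fp$event_id == .x])
  events$areas <- purrr::map(ev$event_id, ~fp$area_px[fp$event_id == .x])
  events$brightness <- purrr::map(ev$event_id,
                                  ~fp$brightness_sum[fp$event_id == .x])
  structure(list(poses = poses, blobs = fp, events = events,
                 background = NULL, heatmap = NULL,
                 body_path = poses[poses$tracked,
                                   c("frame", "center_x", "center_y")],
                 config = cfg, n_frames = max(poses$frame) + 1L),
            class = "gait_track")
}

canonical_parameters <- c(
  "average_speed_cm_s", "frequency_hz", "period_s", "swing_speed_m_s",
  "step_length_mm", "swing_time_s", "stance_time_s", "duty_factor",
  "aep_long_bl", "aep_lat_bl", "pep_long_bl", "pep_lat_bl",
  "footprint_clustering_aep_bl", "footprint_clustering_pep_bl",
  "stance_linearity_bl", "body_linearity_mm",
  "comb_no_swing", "comb_single", "comb_diagonal", "comb_lateral",
  "comb_front_or_hind", "comb_three_leg", "comb_all_legs",
  "phase_fore", "phase_hind",
  "footprint_intensity", "footprint_area_cm2"
)

#' Full gait analysis of a tracked trial
#'
#' Computes the complete per-trial parameter set: speed series, step
#' cycles with timing and duty factor, body-frame stance traces with
#' AEP/PEP, footprint clustering and stance/body linearity, per-frame
#' leg-combination categories and their indexes, contralateral phases,
#' tail kinematics, relative footprint pressure, and the trial summary
#' table. The per-trial mean duty factor averages the four legs' mean
#' cycle duty factors equally; leg-combination categories are evaluated
#' on tracked frames between the first stance onset and the last stance
#' offset.
#'
#' @param track A `gait_track` from [run_track()].
#' @param out_dir Optional directory for the CSV outputs.
#' @param images Also write report images (requires `out_dir`).
#' @return A list of class `gait_analysis`.
#' @export
run_analyze <- function(track, out_dir = NULL, images = FALSE) {
  cfg <- track$config
  poses <- track$poses
  events <- track$events
  speed <- instantaneous_speed(poses, cfg)
  cycles <- build_step_cycles(events, cfg)
  cycles$swing_speed_m_s <- swing_speed(cycles$step_length_mm,
                                        cycles$swing_time)

  usable <- which(vapply(seq_len(nrow(events)),
                         function(i) length(events$frames[[i]]) >= 2,
                         logical(1)))
  traces <- purrr::map(usable, function(i) {
    build_stance_trace(events[i, ], poses)
  })
  aep_pep <- purrr::map_dfr(seq_along(traces), function(k) {
    t <- traces[[k]]
    tibble::tibble(event_id = events$event_id[usable[k]], leg = t$leg[1],
                   aep_long = attr(t, "aep")[["longitudinal"]],
                   aep_lat = attr(t, "aep")[["lateral"]],
                   pep_long = attr(t, "pep")[["longitudinal"]],
                   pep_lat = attr(t, "pep")[["lateral"]],
                   flagged = attr(t, "flagged"))
  })
  clustering_aep <- quiet_na(footprint_clustering(traces, "AEP"))
  clustering_pep <- quiet_na(footprint_clustering(traces, "PEP"))
  linearity <- trial_stance_linearity(traces, cfg$linearity_smooth_win)
  body_lin <- body_linearity_index(poses, cfg, cfg$linearity_smooth_win)

  if (nrow(events)) {
    span <- seq(min(events$onset), max(events$offset))
    flags <- stance_flags(events, span)
    cats <- frame_combination(flags$LF, flags$LH, flags$RF, flags$RH)
    tracked_set <- poses$frame[poses$tracked]
    cats[!(span %in% tracked_set)] <- NA
    per_frame <- tibble::tibble(frame = span, category = cats)
    comb <- combination_indexes(cats)
  } else {
    per_frame <- tibble::tibble(frame = integer(), category = factor())
    comb <- NULL
  }

  phase_fore <- phase_or_null(cycles, events, "LF", "RF")
  phase_hind <- phase_or_null(cycles, events, "LH", "RH")

  tailm <- tail_metrics(poses, cfg)
  pressures <- purrr::map_dfr(seq_len(nrow(events)), function(i) {
    dplyr::mutate(pressure_series(events[i, ], cfg),
                  event_id = events$event_id[i], leg = events$leg[i],
                  .before = 1)
  })
  distances <- footprint_distances(events, poses, cfg)

  summary <- trial_summary(speed, cycles, aep_pep, clustering_aep,
                           clustering_pep, linearity, body_lin, comb,
                           phase_fore, phase_hind, events, cfg)
  analysis <- structure(list(
    speed = speed, cycles = cycles, traces = traces, aep_pep = aep_pep,
    clustering_aep = clustering_aep, clustering_pep = clustering_pep,
    stance_linearity = linearity, body_linearity = body_lin,
    per_frame = per_frame, combination = comb,
    phase_fore = phase_fore, phase_hind = phase_hind,
    tail_metrics = tailm, pressures = pressures, distances = distances,
    summary = summary, config = cfg
  ), class = "gait_analysis")
  if (!is.null(out_dir)) write_analysis(analysis, track, out_dir, images)
  analysis
}

quiet_na <- function(expr) suppressWarnings(expr)

phase_or_null <- function(cycles, events, ref, partner) {
  rc <- cycles[cycles$leg == ref, , drop = FALSE]
  po <- events$onset[!is.na(events$leg) & events$leg == partner]
  tryCatch(contralateral_phase(rc, po), error = function(e) NULL)
}

# per-frame distance of each footprint to the body centre: total and the
# components parallel/perpendicular to the body axis, in cm
footprint_distances <- function(events, poses, cfg) {
  out <- tibble::tibble(event_id = integer(), leg = character(),
                        frame = numeric(), total_cm = numeric(),
                        parallel_cm = numeric(), perpendicular_cm = numeric())
  if (!nrow(events)) return(out)
  tr <- poses[poses$tracked, , drop = FALSE]
  purrr::map_dfr(seq_len(nrow(events)), function(i) {
    fr <- events$frames[[i]]
    keep <- fr %in% tr$frame
    if (!any(keep)) return(out)
    p <- tr[match(fr[keep], tr$frame), ]
    dx <- events$xs[[i]][keep] - p$center_x
    dy <- events$ys[[i]][keep] - p$center_y
    ct <- cos(p$orientation); st <- sin(p$orientation)
    tibble::tibble(event_id = events$event_id[i], leg = events$leg[i],
                   frame = fr[keep],
                   total_cm = sqrt(dx^2 + dy^2) / cfg$px_per_cm,
                   parallel_cm = (dx * ct + dy * st) / cfg$px_per_cm,
                   perpendicular_cm = (-dx * st + dy * ct) / cfg$px_per_cm)
  })
}

trial_summary <- function(speed, cycles, aep_pep, cl_aep, cl_pep, linearity,
                          body_lin, comb, phase_fore, phase_hind, events,
                          cfg) {
  row <- function(p, v, s = NA_real_, flag = NA_character_) {
    tibble::tibble(parameter = p, value = v, sd = s, flag = flag)
  }
  und <- function(p, why) row(p, NA_real_, flag = why)
  ok_cycles <- nrow(cycles) > 0
  rows <- list(row("average_speed_cm_s", attr(speed, "average_cm_s")))
  msd <- function(x) list(m = mean(x, na.rm = TRUE),
                          s = stats::sd(x, na.rm = TRUE))
  if (ok_cycles) {
    leg_duty <- cycles |>
      dplyr::group_by(.data$leg) |>
      dplyr::summarise(d = mean(.data$duty_factor), .groups = "drop")
    ss <- cycles$swing_speed_m_s[!is.na(cycles$swing_speed_m_s)]
    rows <- c(rows, list(
      row("frequency_hz", msd(1 / cycles$period)$m, msd(1 / cycles$period)$s),
      row("period_s", msd(cycles$period)$m, msd(cycles$period)$s),
      row("swing_speed_m_s", mean(ss), stats::sd(ss)),
      row("step_length_mm", msd(cycles$step_length_mm)$m,
          msd(cycles$step_length_mm)$s),
      row("swing_time_s", msd(cycles$swing_time)$m, msd(cycles$swing_time)$s),
      row("stance_time_s", msd(cycles$stance_time)$m,
          msd(cycles$stance_time)$s),
      row("duty_factor", mean(leg_duty$d), stats::sd(leg_duty$d))
    ))
  } else {
    rows <- c(rows, lapply(c("frequency_hz", "period_s", "swing_speed_m_s",
                             "step_length_mm", "swing_time_s",
                             "stance_time_s", "duty_factor"),
                           und, why = "no complete step cycle"))
  }
  if (nrow(aep_pep)) {
    ap <- aep_pep[!aep_pep$flagged, , drop = FALSE]
    if (!nrow(ap)) ap <- aep_pep
    rows <- c(rows, list(
      row("aep_long_bl", mean(ap$aep_long), stats::sd(ap$aep_long)),
      row("aep_lat_bl", mean(ap$aep_lat), stats::sd(ap$aep_lat)),
      row("pep_long_bl", mean(ap$pep_long), stats::sd(ap$pep_long)),
      row("pep_lat_bl", mean(ap$pep_lat), stats::sd(ap$pep_lat))
    ))
  } else {
    rows <- c(rows, lapply(c("aep_long_bl", "aep_lat_bl", "pep_long_bl",
                             "pep_lat_bl"), und, why = "no stance traces"))
  }
  rows <- c(rows, list(
    if (is.na(cl_aep)) und("footprint_clustering_aep_bl", "needs >= 2 steps per leg")
    else row("footprint_clustering_aep_bl", cl_aep),
    if (is.na(cl_pep)) und("footprint_clustering_pep_bl", "needs >= 2 steps per leg")
    else row("footprint_clustering_pep_bl", cl_pep),
    if (is.na(linearity)) und("stance_linearity_bl", "traces shorter than window")
    else row("stance_linearity_bl", linearity),
    if (is.na(body_lin)) und("body_linearity_mm", "too few tracked frames")
    else row("body_linearity_mm", body_lin)
  ))
  if (!is.null(comb)) {
    for (cat in combination_categories) {
      rows <- c(rows, list(row(paste0("comb_", cat), comb[[cat]])))
    }
  } else {
    rows <- c(rows, lapply(paste0("comb_", combination_categories), und,
                           why = "no classified frames"))
  }
  rows <- c(rows, list(
    if (is.null(phase_fore)) und("phase_fore", "no paired fore cycles")
    else row("phase_fore", phase_fore$mean_phase, phase_fore$dispersion),
    if (is.null(phase_hind)) und("phase_hind", "no paired hind cycles")
    else row("phase_hind", phase_hind$mean_phase, phase_hind$dispersion)
  ))
  if (nrow(events)) {
    mb <- vapply(events$brightness, function(b) mean(b, na.rm = TRUE),
                 numeric(1))
    ma <- vapply(events$areas, function(a) mean(a, na.rm = TRUE), numeric(1)) /
      cfg$px_per_cm^2
    rows <- c(rows, list(
      row("footprint_intensity", mean(mb), stats::sd(mb)),
      row("footprint_area_cm2", mean(ma), stats::sd(ma))
    ))
  } else {
    rows <- c(rows, lapply(c("footprint_intensity", "footprint_area_cm2"),
                           und, why = "no footprints"))
  }
  out <- dplyr::bind_rows(rows)
  stopifnot(identical(sort(out$parameter), sort(canonical_parameters)))
  out
}

write_analysis <- function(analysis, track, out_dir, images = FALSE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  sp <- tibble::as_tibble(analysis$speed)
  write_table(sp, file.path(out_dir, "speed.csv"))
  write_table(analysis$cycles, file.path(out_dir, "cycles.csv"))
  tr_df <- purrr::map_dfr(seq_along(analysis$traces), function(k) {
    t <- analysis$traces[[k]]
    tibble::tibble(trace = k, leg = t$leg, frame = t$frame,
                   longitudinal = t$longitudinal, lateral = t$lateral)
  })
  write_table(tr_df, file.path(out_dir, "stance_traces.csv"))
  write_table(analysis$aep_pep, file.path(out_dir, "aep_pep.csv"))
  pf <- analysis$per_frame
  pf$category <- as.character(pf$category)
  write_table(pf, file.path(out_dir, "gait_per_frame.csv"))
  if (!is.null(analysis$combination)) {
    write_table(analysis$combination,
                file.path(out_dir, "combination_indexes.csv"))
  }
  ph <- purrr::map_dfr(c(fore = "phase_fore", hind = "phase_hind"),
                       function(nm) {
    p <- analysis[[nm]]
    if (is.null(p)) {
      tibble::tibble(mean_phase = NA_real_, dispersion = NA_real_, n = 0L)
    } else {
      tibble::tibble(mean_phase = p$mean_phase, dispersion = p$dispersion,
                     n = p$n)
    }
  }, .id = "pair")
  write_table(ph, file.path(out_dir, "phases.csv"))
  write_table(analysis$tail_metrics, file.path(out_dir, "tail_metrics.csv"))
  write_table(analysis$pressures, file.path(out_dir, "pressure.csv"))
  write_table(analysis$distances, file.path(out_dir, "footprint_distances.csv"))
  write_table(analysis$summary, file.path(out_dir, "summary.csv"))
  if (images) write_report_images(analysis, track, out_dir)
  invisible(out_dir)
}

#' @export
print.gait_analysis <- function(x, ...) {
  cat("Gait analysis\n")
  cat(sprintf("  average speed %.1f cm/s, %d step cycles\n",
              attr(x$speed, "average_cm_s"), nrow(x$cycles)))
  d <- x$summary$value[x$summary$parameter == "duty_factor"]
  if (!is.na(d)) {
    cat(sprintf("  mean duty factor %.3f (%s)\n", d, classify_gait_regime(d)))
  }
  invisible(x)
}
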