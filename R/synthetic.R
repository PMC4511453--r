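#' Specification of a synthetic fTIR walking trial
#'
#' Defines the study conditions for a ground-truthed synthetic trial: a
#' straight walk along the walkway at a set speed, a four-leg stance
#' schedule (trot-like diagonal pairing by default), and the rendering
#' geometry and noise. Defaults emulate an adult mouse on a 250 Hz fTIR
#' walkway: 7 cm body, 7 cm tail, stride frequency rising from roughly 4
#' to 8 Hz over the 10-80 cm/s speed range (so stride length grows with
#' speed), and duty factor declining linearly with speed through the
#' walk-to-run transition.
#'
#' @param speed_cm_s Average walking speed.
#' @param duty Duty factor; default follows a linear decline with speed
#'   crossing 0.5 near 53 cm/s.
#' @param stride_cm Stride (step) length; default `speed / (3.5 + 0.07 speed)`,
#'   i.e. a stride frequency of 3.5 + 0.07 v Hz.
#' @param pair_phase Contralateral phase offset (0.5 = anti-phase trot).
#' @param diagonal TRUE for diagonal pairing (trot family), FALSE for
#'   lateral pairing (pace family).
#' @param body_length_cm,body_width_cm,tail_length_cm Animal geometry.
#' @param frame_rate_hz,px_per_cm Acquisition parameters.
#' @param n_cycles Number of stride cycles to schedule.
#' @param color TRUE renders colour frames (body in the red channel, paws
#'   in green); FALSE renders grayscale.
#' @param pixel_noise_sd Additive Gaussian pixel noise (8-bit units).
#' @param aep_jitter_mm SD of the paw-placement (touchdown) jitter.
#' @param pep_jitter_mm SD of the liftoff-position jitter, realised as
#'   stance-duration jitter of the floor-anchored print.
#' @param speed_mod_amp,speed_mod_hz Fractional amplitude and frequency of
#'   sinusoidal speed modulation (0 = constant speed).
#' @param tail_sway_amp_cm,tail_sway_hz Amplitude (at the tail tip) and
#'   frequency of sinusoidal tail sway.
#' @param seed Integer RNG seed; a fixed seed makes the whole trial
#'   byte-reproducible.
#' @return A list of class `gait_spec`.
#' @export
gait_spec <- function(speed_cm_s = 30,
                      duty = NULL,
                      stride_cm = NULL,
                      pair_phase = 0.5,
                      diagonal = TRUE,
                      body_length_cm = 7,
                      body_width_cm = 2.5,
                      tail_length_cm = 7,
                      frame_rate_hz = 250,
                      px_per_cm = 8,
                      n_cycles = 12,
                      color = FALSE,
                      pixel_noise_sd = 2,
                      aep_jitter_mm = 0.5,
                      pep_jitter_mm = 1.0,
                      speed_mod_amp = 0,
                      speed_mod_hz = 5,
                      tail_sway_amp_cm = 0.25,
                      tail_sway_hz = 2,
                      seed = 1) {
  if (is.null(duty)) duty <- min(0.9, max(0.2, 0.6425 - 0.0027 * speed_cm_s))
  if (is.null(stride_cm)) stride_cm <- speed_cm_s / (3.5 + 0.07 * speed_cm_s)
  stopifnot(speed_cm_s > 0, duty > 0, duty < 1, stride_cm > 0,
            pair_phase >= 0, pair_phase < 1, n_cycles >= 2,
            frame_rate_hz > 0, px_per_cm > 0)
  structure(list(
    speed_cm_s = speed_cm_s, duty = duty, stride_cm = stride_cm,
    pair_phase = pair_phase, diagonal = diagonal,
    body_length_cm = body_length_cm, body_width_cm = body_width_cm,
    tail_length_cm = tail_length_cm,
    frame_rate_hz = frame_rate_hz, px_per_cm = px_per_cm,
    n_cycles = n_cycles, color = color,
    pixel_noise_sd = pixel_noise_sd,
    aep_jitter_mm = aep_jitter_mm, pep_jitter_mm = pep_jitter_mm,
    speed_mod_amp = speed_mod_amp, speed_mod_hz = speed_mod_hz,
    tail_sway_amp_cm = tail_sway_amp_cm, tail_sway_hz = tail_sway_hz,
    seed = as.integer(seed)
  ), class = "gait_spec")
}

# rendering geometry shared by the generator and the ground-truth masks
synth_geometry <- function(spec) {
  px <- spec$px_per_cm
  list(
    bg_level = 30, body_level = 110, paw_amp = 240,
    paw_sigma_px = 0.28 * px,
    paw_shift_px = 0.45 * px,      # rostral pressure shift toward the toes
    paw_shift_amp = 0.5,           # relative amplitude of the toe component
    tail_base_hw = 0.225 * px,     # tail half-width at the base
    tail_tip_hw = 0.075 * px,
    # paw placement in body-length units (longitudinal, |lateral|)
    fore_long = 0.33, fore_lat = 0.10,
    hind_long = -0.10, hind_lat = 0.22,
    margin_cm = 2.5, arena_height_cm = 6
  )
}

# leg phase table for the requested pairing
leg_phase_table <- function(spec) {
  pp <- spec$pair_phase
  if (spec$diagonal) {
    c(LF = 0, RH = 0, RF = pp, LH = pp)
  } else {
    c(LF = 0, LH = 0, RF = pp, RH = pp)
  }
}

#' Generate the ground truth of a synthetic trial
#'
#' Produces the exact per-frame body pose, the per-leg stance schedule
#' with floor-anchored paw positions, the static background field, and
#' the true parameter values (duty factor, stride, contralateral phases,
#' average speed) recomputed from the emitted schedule — so recovery
#' errors measured against this truth reflect tracking error only, not
#' frame quantisation.
#'
#' @param spec A [gait_spec()].
#' @return A list of class `gait_truth` with elements `spec`, `poses`,
#'   `schedule`, `params`, `background`, `geometry`, `n_frames`, `width`,
#'   `height`.
#' @export
generate_ground_truth <- function(spec) {
  stopifnot(inherits(spec, "gait_spec"))
  if (spec$n_cycles < 2) stop("spec must yield at least 2 cycles", call. = FALSE)
  geom <- synth_geometry(spec)
  px <- spec$px_per_cm; fps <- spec$frame_rate_hz
  withr::local_seed(spec$seed)

  period_f <- max(8L, as.integer(round(spec$stride_cm / spec$speed_cm_s * fps)))
  n_frames <- as.integer(ceiling((spec$n_cycles + 1.25) * period_f))
  t <- (seq_len(n_frames) - 1L) / fps
  v <- spec$speed_cm_s *
    (1 + spec$speed_mod_amp * sin(2 * pi * spec$speed_mod_hz * t))
  x_cm <- cumsum(v / fps) - v[1] / fps  # centre advance from 0

  L_px <- spec$body_length_cm * px
  x0_cm <- geom$margin_cm + spec$tail_length_cm + spec$body_length_cm / 2
  cx <- (x0_cm + x_cm) * px
  height <- as.integer(ceiling(geom$arena_height_cm * px))
  cy <- rep(height / 2, n_frames)
  width <- as.integer(ceiling((x0_cm + x_cm[n_frames] +
                                 spec$body_length_cm / 2 + geom$margin_cm +
                                 geom$fore_long * spec$body_length_cm) * px))

  alpha0 <- asin(min(0.95, spec$tail_sway_amp_cm / spec$tail_length_cm))
  alpha <- alpha0 * sin(2 * pi * spec$tail_sway_hz * t)
  base_x <- cx - L_px / 2
  tail_len_px <- spec$tail_length_cm * px
  tail_pt <- function(fr) {  # fraction of tail arc length
    s <- fr * tail_len_px
    list(x = base_x - s * cos(alpha), y = cy - s * sin(alpha))
  }
  t1 <- tail_pt(0.25); t2 <- tail_pt(0.50); t3 <- tail_pt(0.75)

  poses <- tibble::tibble(
    frame = seq_len(n_frames) - 1L,
    center_x = cx, center_y = cy, orientation = 0,
    nose_x = cx + L_px / 2, nose_y = cy,
    tailbase_x = base_x, tailbase_y = cy,
    tail1_x = t1$x, tail1_y = t1$y,
    tail2_x = t2$x, tail2_y = t2$y,
    tail3_x = t3$x, tail3_y = t3$y,
    tail_angle = alpha,
    body_length_cm = spec$body_length_cm,
    body_length_px = L_px
  )

  phases <- leg_phase_table(spec)
  base_stance <- max(3L, as.integer(round(spec$duty * period_f)))
  pep_sd_frames <- (spec$pep_jitter_mm / 10) / (spec$speed_cm_s / fps)
  aep_sd_px <- spec$aep_jitter_mm / 10 * px

  sched <- list()
  for (leg in leg_ids) {
    side <- substr(leg, 1, 1); part <- substr(leg, 2, 2)
    long_off <- if (part == "F") geom$fore_long else geom$hind_long
    lat_off <- (if (part == "F") geom$fore_lat else geom$hind_lat) *
      (if (side == "L") 1 else -1)
    ph <- phases[[leg]]
    for (k in 0:spec$n_cycles) {
      onset <- as.integer(round((k + ph) * period_f))
      stance <- base_stance +
        as.integer(round(stats::rnorm(1, 0, pep_sd_frames)))
      stance <- max(3L, min(stance, period_f - 3L))
      offset <- onset + stance - 1L
      if (onset < 0L || offset > n_frames - 1L) next
      ax <- cx[onset + 1L] + long_off * L_px + stats::rnorm(1, 0, aep_sd_px)
      ay <- cy[onset + 1L] + lat_off * L_px + stats::rnorm(1, 0, aep_sd_px)
      sched[[length(sched) + 1L]] <- tibble::tibble(
        leg = leg, cycle = k, onset = onset, offset = offset,
        anchor_x = ax, anchor_y = ay,
        aep_long = (ax - cx[onset + 1L]) / L_px,
        aep_lat = (ay - cy[onset + 1L]) / L_px,
        pep_long = (ax - cx[offset + 1L]) / L_px,
        pep_lat = (ay - cy[offset + 1L]) / L_px
      )
    }
  }
  schedule <- dplyr::arrange(dplyr::bind_rows(sched), .data$onset, .data$leg)

  params <- truth_params(schedule, poses, spec, period_f)
  background <- matrix(geom$bg_level, height, width)
  structure(list(
    spec = spec, poses = poses, schedule = schedule, params = params,
    background = background, geometry = geom,
    n_frames = n_frames, width = width, height = height,
    period_frames = period_f
  ), class = "gait_truth")
}

# true parameter values recomputed from the emitted schedule
truth_params <- function(schedule, poses, spec, period_f) {
  fps <- spec$frame_rate_hz
  leg_duty <- function(onset, offset) {
    if (length(onset) < 2) return(NA_real_)
    mean((utils::head(offset, -1) - utils::head(onset, -1) + 1) / diff(onset))
  }
  leg_stride <- function(x, y) {
    if (length(x) < 2) return(NA_real_)
    mean(sqrt(diff(x)^2 + diff(y)^2))
  }
  per_leg <- schedule |>
    dplyr::group_by(.data$leg) |>
    dplyr::arrange(.data$onset, .by_group = TRUE) |>
    dplyr::summarise(
      n_stances = dplyr::n(),
      duty = leg_duty(.data$onset, .data$offset),
      stride_cm = leg_stride(.data$anchor_x, .data$anchor_y) / spec$px_per_cm,
      .groups = "drop")
  n <- nrow(poses)
  avg_speed <- sqrt((poses$center_x[n] - poses$center_x[1])^2 +
                      (poses$center_y[n] - poses$center_y[1])^2) /
    spec$px_per_cm / ((n - 1) / fps)
  phase_pair <- function(ref, partner) {
    on_r <- sort(schedule$onset[schedule$leg == ref])
    on_p <- sort(schedule$onset[schedule$leg == partner])
    ph <- numeric(0)
    for (i in seq_len(length(on_r) - 1)) {
      hit <- on_p[on_p >= on_r[i] & on_p < on_r[i + 1]]
      if (length(hit)) ph <- c(ph, (hit[1] - on_r[i]) / (on_r[i + 1] - on_r[i]))
    }
    if (!length(ph)) return(NA_real_)
    circular_phase_stats(ph)$mean_phase
  }
  list(
    per_leg = per_leg,
    duty = mean(per_leg$duty, na.rm = TRUE),
    stride_cm = mean(per_leg$stride_cm, na.rm = TRUE),
    step_length_mm = mean(per_leg$stride_cm, na.rm = TRUE) * 10,
    avg_speed_cm_s = avg_speed,
    phase_fore = phase_pair("LF", "RF"),
    phase_hind = phase_pair("LH", "RH"),
    period_s = period_f / fps
  )
}

#' Render the frame sequence of a synthetic trial
#'
#' Draws each frame as a dark background plus a mid-intensity body
#' ellipse with a tapered tail, and — only while a leg is in stance, as on
#' a real fTIR walkway — a bright Gaussian paw spot anchored to the floor.
#' The spot's amplitude ramps up over the first 10 % of the stance,
#' plateaus, and over the final third a second component grows rostrally
#' of the anchor, shifting the brightness centroid toward the toes.
#' Gaussian pixel noise is added last and values are clipped to 0-255.
#'
#' @param truth A `gait_truth` from [generate_ground_truth()].
#' @param spec The matching [gait_spec()]; defaults to `truth$spec`.
#' @return List of `gait_frame` objects.
#' @export
render_frames <- function(truth, spec = truth$spec) {
  stopifnot(inherits(truth, "gait_truth"))
  geom <- truth$geometry
  withr::local_seed(spec$seed + 1L)
  sched <- truth$schedule
  frames <- vector("list", truth$n_frames)
  for (i in seq_len(truth$n_frames)) {
    f <- i - 1L
    silmat <- render_silhouette(truth, i, value = geom$body_level,
                                base = truth$background)
    pawmat <- matrix(0, truth$height, truth$width)
    act <- sched[sched$onset <= f & sched$offset >= f, , drop = FALSE]
    for (j in seq_len(nrow(act))) {
      pawmat <- render_paw(pawmat, act[j, ], f, geom)
    }
    if (spec$color) {
      arr <- array(geom$bg_level, c(truth$height, truth$width, 3L))
      arr[, , 1] <- silmat
      arr[, , 2] <- pmin(255, geom$bg_level + pawmat)
      px <- arr
    } else {
      px <- pmin(pmax(silmat, pawmat), 255)
    }
    if (spec$pixel_noise_sd > 0) {
      px <- px + stats::rnorm(length(px), 0, spec$pixel_noise_sd)
      px[px < 0] <- 0; px[px > 255] <- 255
    }
    frames[[i]] <- new_frame(f, round(px), spec$frame_rate_hz)
  }
  frames
}

# body ellipse + tapered straight tail drawn onto `base`
render_silhouette <- function(truth, i, value, base) {
  p <- truth$poses[i, ]
  geom <- truth$geometry
  spec <- truth$spec
  px <- spec$px_per_cm
  mat <- base
  a <- spec$body_length_cm / 2 * px
  b <- spec$body_width_cm / 2 * px
  win <- pixel_window(p$center_x, p$center_y, a + 2, b + 2,
                      truth$height, truth$width)
  if (!is.null(win)) {
    inside <- ((win$X - p$center_x) / a)^2 + ((win$Y - p$center_y) / b)^2 <= 1
    blk <- mat[win$rows, win$cols]
    blk[inside] <- value
    mat[win$rows, win$cols] <- blk
  }
  # straight tail at angle pi +/- alpha from the base
  len <- spec$tail_length_cm * px
  dirv <- c(-cos(p$tail_angle), -sin(p$tail_angle))
  bx <- p$tailbase_x; by <- p$tailbase_y
  ex <- bx + len * dirv[1]; ey <- by + len * dirv[2]
  win <- pixel_window((bx + ex) / 2, (by + ey) / 2,
                      abs(ex - bx) / 2 + geom$tail_base_hw + 2,
                      abs(ey - by) / 2 + geom$tail_base_hw + 2,
                      truth$height, truth$width)
  if (!is.null(win)) {
    rx <- win$X - bx; ry <- win$Y - by
    tp <- pmax(0, pmin(len, rx * dirv[1] + ry * dirv[2]))
    dperp <- sqrt((rx - tp * dirv[1])^2 + (ry - tp * dirv[2])^2)
    hw <- geom$tail_base_hw + (geom$tail_tip_hw - geom$tail_base_hw) * tp / len
    inside <- dperp <= hw
    blk <- mat[win$rows, win$cols]
    blk[inside] <- value
    mat[win$rows, win$cols] <- blk
  }
  mat
}

# 0-based coordinate grids for a clipped rectangular window
pixel_window <- function(cx, cy, half_w, half_h, H, W) {
  c0 <- max(0L, as.integer(floor(cx - half_w)))
  c1 <- min(W - 1L, as.integer(ceiling(cx + half_w)))
  r0 <- max(0L, as.integer(floor(cy - half_h)))
  r1 <- min(H - 1L, as.integer(ceiling(cy + half_h)))
  if (c0 > c1 || r0 > r1) return(NULL)
  cols <- (c0:c1) + 1L; rows <- (r0:r1) + 1L
  list(rows = rows, cols = cols,
       X = matrix(rep(c0:c1, each = length(rows)), length(rows)),
       Y = matrix(rep(r0:r1, times = length(cols)), length(rows)))
}

# paw spot with onset ramp and rostral (toe-ward) late-stance component
render_paw <- function(mat, st, f, geom) {
  dur <- st$offset - st$onset
  u <- if (dur > 0) (f - st$onset) / dur else 1
  amp_rel <- if (u <= 0.1) 0.85 + 1.5 * u else 1
  sg <- geom$paw_sigma_px
  H <- nrow(mat); W <- ncol(mat)
  win <- pixel_window(st$anchor_x, st$anchor_y, 4 * sg + geom$paw_shift_px,
                      4 * sg, H, W)
  if (is.null(win)) return(mat)
  g <- geom$paw_amp * amp_rel *
    exp(-((win$X - st$anchor_x)^2 + (win$Y - st$anchor_y)^2) / (2 * sg^2))
  w2 <- max(0, (u - 2 / 3) * 3)
  if (w2 > 0) {
    # additive toe component: loading transfers rostrally without the
    # combined spot ever splitting into two blobs
    g <- g + geom$paw_amp * amp_rel * geom$paw_shift_amp * w2 *
      exp(-((win$X - st$anchor_x - geom$paw_shift_px)^2 +
              (win$Y - st$anchor_y)^2) / (2 * sg^2))
  }
  blk <- mat[win$rows, win$cols]
  mat[win$rows, win$cols] <- pmax(blk, g)
  mat
}

#' Ground-truth body silhouette mask
#'
#' Logical mask of the rendered body (ellipse plus tail) for one frame,
#' for validating segmentation against the generator.
#'
#' @param truth A `gait_truth`.
#' @param frame_index 0-based frame number.
#' @return Logical `height x width` matrix.
#' @export
truth_body_mask <- function(truth, frame_index) {
  m <- render_silhouette(truth, frame_index + 1L, value = 1,
                         base = matrix(0, truth$height, truth$width))
  m > 0
}

#' Default tracking configuration for synthetic trials
#'
#' Thresholds matched to the renderer's intensity levels (background 30,
#' body 110, paw spots up to 240).
#'
#' @param spec A [gait_spec()].
#' @return A [gait_config()] list.
#' @export
synthetic_config <- function(spec) {
  if (spec$color) {
    gait_config(frame_rate_hz = spec$frame_rate_hz, px_per_cm = spec$px_per_cm,
                bg_tolerance = 12,
                body_min = c(70, 0, 0), body_max = c(160, 149, 90),
                footprint_min = c(0, 150, 0), footprint_max = c(255, 255, 255))
  } else {
    gait_config(frame_rate_hz = spec$frame_rate_hz, px_per_cm = spec$px_per_cm)
  }
}

#' Simulate a complete synthetic trial
#'
#' @param spec A [gait_spec()].
#' @param render TRUE to also render the frame sequence.
#' @return List with `truth`, `frames` (NULL when `render = FALSE`) and
#'   `config` (a matching [gait_config()]).
#' @export
simulate_trial <- function(spec, render = TRUE) {
  truth <- generate_ground_truth(spec)
  frames <- if (render) render_frames(truth, spec) else NULL
  list(truth = truth, frames = frames, config = synthetic_config(spec))
}

#' Write a synthetic trial to disk as a fixture
#'
#' Writes zero-padded numbered PNG frames, the matching configuration
#' file, and the ground-truth tables (`truth_poses.csv`,
#' `truth_schedule.csv`, `truth_params.csv`). Re-running with the same
#' seed reproduces byte-identical CSVs.
#'
#' @param trial Output of [simulate_trial()] (with rendered frames).
#' @param dir Destination directory.
#' @param overwrite Allow writing into an existing non-empty directory.
#' @return `dir`, invisibly.
#' @export
write_fixture <- function(trial, dir, overwrite = FALSE) {
  if (dir.exists(dir) && length(list.files(dir)) && !overwrite) {
    stop("directory not empty (use overwrite = TRUE): ", dir, call. = FALSE)
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  stopifnot(!is.null(trial$frames))
  for (fr in trial$frames) {
    png::writePNG(fr$pixels / 255,
                  file.path(dir, sprintf("frame_%06d.png", fr$index)))
  }
  write_gait_config(trial$config, file.path(dir, "config.yaml"))
  tr <- trial$truth
  readr::write_csv(tr$poses, file.path(dir, "truth_poses.csv"))
  readr::write_csv(tr$schedule, file.path(dir, "truth_schedule.csv"))
  pp <- tr$params
  readr::write_csv(
    tibble::tibble(parameter = c("duty", "stride_cm", "step_length_mm",
                                 "avg_speed_cm_s", "phase_fore", "phase_hind",
                                 "period_s"),
                   value = c(pp$duty, pp$stride_cm, pp$step_length_mm,
                             pp$avg_speed_cm_s, pp$phase_fore, pp$phase_hind,
                             pp$period_s)),
    file.path(dir, "truth_params.csv"))
  invisible(dir)
}
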