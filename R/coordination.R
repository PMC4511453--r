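#' Transform a pixel point into the body frame
#'
#' Translates by the body centre, rotates by the body orientation and
#' normalises by body length. The longitudinal axis is positive toward the
#' nose; the lateral axis is positive toward the animal's left in the
#' bottom-view imaging convention (image y grows downward, the camera sees
#' the animal from below, so anatomical left appears on the +y side of the
#' heading).
#'
#' @param x,y Pixel coordinates (vectorised).
#' @param pose One-row pose tibble with valid `center_x`, `center_y`,
#'   `orientation`, `body_length_px`.
#' @return Tibble with columns `longitudinal`, `lateral` in body-length
#'   units.
#' @export
to_body_frame <- function(x, y, pose) {
  L <- pose$body_length_px
  if (is.na(L) || L <= 0) stop("pose body length must be > 0", call. = FALSE)
  dx <- x - pose$center_x
  dy <- y - pose$center_y
  ct <- cos(pose$orientation); st <- sin(pose$orientation)
  tibble::tibble(
    longitudinal = (dx * ct + dy * st) / L,
    lateral = (-dx * st + dy * ct) / L
  )
}

#' Inverse body-frame transform
#'
#' @param longitudinal,lateral Body-frame coordinates in body-length
#'   units (vectorised).
#' @param pose One-row pose tibble.
#' @return Tibble with pixel columns `x`, `y`.
#' @export
from_body_frame <- function(longitudinal, lateral, pose) {
  L <- pose$body_length_px
  if (is.na(L) || L <= 0) stop("pose body length must be > 0", call. = FALSE)
  ct <- cos(pose$orientation); st <- sin(pose$orientation)
  u <- longitudinal * L; v <- lateral * L
  tibble::tibble(
    x = pose$center_x + u * ct - v * st,
    y = pose$center_y + u * st + v * ct
  )
}

#' Body-frame stance trace of one event
#'
#' Transforms the per-frame footprint centroid into the body frame of each
#' stance frame, yielding the trace from touchdown (anterior extreme
#' position, AEP) to liftoff (posterior extreme position, PEP). Frames
#' with missing poses are interpolated linearly in centre and orientation;
#' traces with fewer than 80 % tracked frames are flagged and should be
#' excluded from aggregates.
#'
#' @param event One-row event tibble (one row of [link_blobs()] output).
#' @param poses Per-frame pose tibble.
#' @return Tibble of class `stance_trace` (`leg`, `frame`, `longitudinal`,
#'   `lateral`) with attributes `aep`, `pep` (named vectors) and `flagged`.
#' @export
build_stance_trace <- function(event, poses) {
  fr <- event$frames[[1]]
  xs <- event$xs[[1]]; ys <- event$ys[[1]]
  tr <- poses[poses$tracked, , drop = FALSE]
  have <- fr %in% tr$frame
  flagged <- mean(have) < 0.8
  sub <- tr[tr$frame >= min(fr) - 20 & tr$frame <= max(fr) + 20, , drop = FALSE]
  if (nrow(sub) < 2) stop("no tracked poses near stance event", call. = FALSE)
  cx <- stats::approx(sub$frame, sub$center_x, xout = fr, rule = 2)$y
  cy <- stats::approx(sub$frame, sub$center_y, xout = fr, rule = 2)$y
  # interpolate orientation on the unwrapped angle to survive wrapping
  th <- stats::approx(sub$frame, unwrap_angles(sub$orientation), xout = fr,
                      rule = 2)$y
  L <- stats::approx(sub$frame, sub$body_length_px, xout = fr, rule = 2)$y
  dx <- xs - cx; dy <- ys - cy
  pts <- tibble::tibble(
    leg = event$leg %||% NA_character_,
    frame = fr,
    longitudinal = (dx * cos(th) + dy * sin(th)) / L,
    lateral = (-dx * sin(th) + dy * cos(th)) / L
  )
  n <- nrow(pts)
  structure(pts,
            aep = c(longitudinal = pts$longitudinal[1], lateral = pts$lateral[1]),
            pep = c(longitudinal = pts$longitudinal[n], lateral = pts$lateral[n]),
            flagged = flagged,
            class = c("stance_trace", class(pts)))
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0 || all(is.na(a))) b else a

unwrap_angles <- function(a) {
  if (length(a) < 2) return(a)
  d <- diff(a)
  d <- d - 2 * pi * round(d / (2 * pi))
  a[1] + c(0, cumsum(d))
}

#' Stance linearity index
#'
#' Mean Euclidean distance between a stance trace and its smoothed version
#' (centred moving average, window shrunk symmetrically at the trace
#' ends). A straight, evenly spaced trace scores exactly 0; lateral jitter
#' of the body raises the index.
#'
#' @param trace A `stance_trace` (or any tibble with `longitudinal` and
#'   `lateral` columns).
#' @param smooth_win Moving-average window in frames.
#' @return Non-negative index in body-length units; `NA` when the trace is
#'   shorter than `smooth_win` points.
#' @export
stance_linearity_index <- function(trace, smooth_win = 15) {
  n <- nrow(trace)
  if (n < smooth_win) return(NA_real_)
  sl <- moving_average(trace$longitudinal, smooth_win)
  st <- moving_average(trace$lateral, smooth_win)
  mean(sqrt((trace$longitudinal - sl)^2 + (trace$lateral - st)^2))
}

#' Trial-level stance linearity
#'
#' Flat mean of [stance_linearity_index()] over all unflagged traces of
#' all legs (the average jitter of the stance traces).
#'
#' @param traces List of `stance_trace` objects.
#' @param smooth_win Moving-average window in frames.
#' @return Mean index in body-length units, `NA` if no trace qualifies.
#' @export
trial_stance_linearity <- function(traces, smooth_win = 15) {
  traces <- traces[!vapply(traces, function(t) isTRUE(attr(t, "flagged")),
                           logical(1))]
  vals <- vapply(traces, stance_linearity_index, numeric(1),
                 smooth_win = smooth_win)
  if (all(is.na(vals))) NA_real_ else mean(vals, na.rm = TRUE)
}

#' Footprint clustering (AEP or PEP spread)
#'
#' Per leg with at least two steps, the 2-D standard distance of the
#' chosen stance-trace endpoint across steps — the square root of the sum
#' of the population variances of the longitudinal and lateral
#' coordinates. The trial value is the mean over qualifying legs. Smaller
#' values mean more consistent foot placement.
#'
#' @param traces List of `stance_trace` objects for one trial.
#' @param endpoint `"AEP"` (touchdown) or `"PEP"` (liftoff).
#' @return Clustering value in body-length units; `NA` (with a warning)
#'   when no leg has two steps.
#' @export
footprint_clustering <- function(traces, endpoint = c("AEP", "PEP")) {
  endpoint <- match.arg(endpoint)
  at <- tolower(endpoint)
  df <- purrr::map_dfr(traces, function(t) {
    e <- attr(t, at)
    tibble::tibble(leg = t$leg[1], longitudinal = e[["longitudinal"]],
                   lateral = e[["lateral"]])
  })
  if (!nrow(df)) {
    warning("no leg has >= 2 steps; clustering undefined")
    return(NA_real_)
  }
  df <- df[!is.na(df$leg), , drop = FALSE]
  per_leg <- df |>
    dplyr::group_by(.data$leg) |>
    dplyr::filter(dplyr::n() >= 2) |>
    dplyr::summarise(
      sd2 = sqrt(pop_var(.data$longitudinal) + pop_var(.data$lateral)),
      .groups = "drop")
  if (!nrow(per_leg)) {
    warning("no leg has >= 2 steps; clustering undefined")
    return(NA_real_)
  }
  mean(per_leg$sd2)
}

pop_var <- function(x) mean((x - mean(x))^2)

leg_ids <- c("LF", "LH", "RF", "RH")

combination_categories <- c("no_swing", "single", "diagonal", "lateral",
                            "front_or_hind", "three_leg", "all_legs")

#' Leg-combination category of one frame
#'
#' Maps the four per-leg stance flags to one of seven swing categories:
#' no swing, single-leg swing, diagonal-leg swing, lateral-leg swing (both
#' left or both right), front-or-hind swing (both fore or both hind),
#' three-leg swing, all-legs swing. Total over all 16 flag combinations.
#'
#' @param lf,lh,rf,rh Logical stance flags (TRUE = leg in stance),
#'   vectorised.
#' @return Factor with the seven category levels.
#' @export
frame_combination <- function(lf, lh, rf, rh) {
  sw_lf <- !lf; sw_lh <- !lh; sw_rf <- !rf; sw_rh <- !rh
  s <- sw_lf + sw_lh + sw_rf + sw_rh
  out <- character(length(s))
  out[s == 0] <- "no_swing"
  out[s == 1] <- "single"
  out[s == 3] <- "three_leg"
  out[s == 4] <- "all_legs"
  two <- s == 2
  out[two & sw_lf & sw_rh] <- "diagonal"
  out[two & sw_rf & sw_lh] <- "diagonal"
  out[two & sw_lf & sw_lh] <- "lateral"
  out[two & sw_rf & sw_rh] <- "lateral"
  out[two & sw_lf & sw_rf] <- "front_or_hind"
  out[two & sw_lh & sw_rh] <- "front_or_hind"
  factor(out, levels = combination_categories)
}

#' Leg-combination indexes of a trial
#'
#' Fraction of classified frames in each of the seven swing categories;
#' unclassifiable (untracked) frames are excluded from the denominator.
#'
#' @param categories Factor/character vector of per-frame categories
#'   (`NA` = unclassified).
#' @return One-row tibble with the seven category fractions (sum = 1).
#' @export
combination_indexes <- function(categories) {
  categories <- categories[!is.na(categories)]
  if (!length(categories)) stop("no classified frames", call. = FALSE)
  tab <- table(factor(categories, levels = combination_categories))
  fr <- stats::setNames(as.numeric(tab) / length(categories),
                        combination_categories)
  tibble::as_tibble(as.list(fr))
}

#' Per-frame stance flags from stance events
#'
#' Stance intervals (post gap-filling) give flicker-free per-frame flags.
#'
#' @param events Labelled event tibble.
#' @param frames Integer vector of frame numbers to flag.
#' @return Tibble `frame`, `LF`, `LH`, `RF`, `RH` (logical).
#' @export
stance_flags <- function(events, frames) {
  out <- tibble::tibble(frame = frames)
  for (leg in leg_ids) {
    e <- events[!is.na(events$leg) & events$leg == leg, , drop = FALSE]
    fl <- rep(FALSE, length(frames))
    for (i in seq_len(nrow(e))) {
      fl <- fl | (frames >= e$onset[i] & frames <= e$offset[i])
    }
    out[[leg]] <- fl
  }
  out
}

#' Circular mean and dispersion of cycle phases
#'
#' Phases (fractions of a cycle) are mapped to angles, averaged on the
#' circle, and the dispersion is the circular standard deviation
#' `sqrt(-2 log R)`, both re-expressed as cycle fractions.
#'
#' @param phases Numeric vector of phases in [0, 1).
#' @return List with `mean_phase` in [0, 1), `dispersion` (cycle
#'   fractions), `n`.
#' @export
circular_phase_stats <- function(phases) {
  stopifnot(length(phases) >= 1)
  a <- 2 * pi * phases
  C <- mean(cos(a)); S <- mean(sin(a))
  R <- sqrt(C^2 + S^2)
  mu <- atan2(S, C) / (2 * pi)
  mu <- mu %% 1
  if (1 - mu < 1e-9) mu <- 0   # numerically at the wrap point
  disp <- if (R >= 1 - 1e-15) 0 else sqrt(-2 * log(R)) / (2 * pi)
  list(mean_phase = mu, dispersion = disp, n = length(phases))
}

#' Contralateral phase between a leg pair
#'
#' For each reference-leg cycle (stance onset to next stance onset), the
#' phase of the partner leg is the fractional position of the partner's
#' stance onset inside that cycle; cycles containing no partner onset are
#' skipped. Summary statistics are circular, so anti-phase coordination
#' near 0.5 and in-phase coordination near 0/1 are both handled correctly.
#'
#' @param ref_cycles Cycle tibble of the reference leg (from
#'   [build_step_cycles()]).
#' @param partner_onsets Numeric vector of the partner leg's stance onset
#'   frames.
#' @return List of class `phase_estimate`: `mean_phase`, `dispersion`,
#'   `n`, `phases`.
#' @export
contralateral_phase <- function(ref_cycles, partner_onsets) {
  if (nrow(ref_cycles) < 1) stop("need at least one reference cycle", call. = FALSE)
  phases <- numeric(0)
  for (i in seq_len(nrow(ref_cycles))) {
    t0 <- ref_cycles$stance_onset[i]
    t1 <- ref_cycles$next_onset[i]
    hit <- partner_onsets[partner_onsets >= t0 & partner_onsets < t1]
    if (length(hit)) phases <- c(phases, (hit[1] - t0) / (t1 - t0))
  }
  if (length(phases) < 1) stop("no partner onsets inside any reference cycle",
                               call. = FALSE)
  st <- circular_phase_stats(phases)
  structure(c(st, list(phases = phases)), class = "phase_estimate")
}

#' Tail kinematics
#'
#' Per frame: orientation of each stored tail segment relative to the body
#' axis, proximal and distal segment orientations relative to the middle
#' segment, and the perpendicular velocity of the middle tail point —
#' its frame-to-frame displacement projected on the body-frame lateral
#' axis, in cm/s.
#'
#' @param poses Per-frame pose tibble with tail fields.
#' @param cfg A [gait_config()] list.
#' @return Tibble with one row per frame: `frame`, `tail1_vs_body`,
#'   `tail2_vs_body`, `tail3_vs_body` (radians), `proximal_vs_middle`,
#'   `distal_vs_middle`, `perp_velocity_cm_s` (`NA` where the tail is
#'   missing).
#' @export
tail_metrics <- function(poses, cfg) {
  p <- poses
  for (col in c("tail1_or", "tail2_or", "tail3_or", "tail2_x", "tail2_y",
                "has_tail")) {
    if (!col %in% names(p)) {
      p[[col]] <- if (col == "has_tail") FALSE else NA_real_
    }
  }
  rel <- function(a, b) wrap_angle(a - b)
  out <- tibble::tibble(
    frame = p$frame,
    tail1_vs_body = rel(p$tail1_or, p$orientation),
    tail2_vs_body = rel(p$tail2_or, p$orientation),
    tail3_vs_body = rel(p$tail3_or, p$orientation),
    proximal_vs_middle = rel(p$tail1_or, p$tail2_or),
    distal_vs_middle = rel(p$tail3_or, p$tail2_or),
    perp_velocity_cm_s = NA_real_
  )
  ok <- p$tracked & p$has_tail & !is.na(p$tail2_x)
  idx <- which(ok)
  if (length(idx) >= 2) {
    for (k in 2:length(idx)) {
      i <- idx[k]; j <- idx[k - 1]
      if (p$frame[i] - p$frame[j] != 1) next
      dx <- p$tail2_x[i] - p$tail2_x[j]
      dy <- p$tail2_y[i] - p$tail2_y[j]
      th <- p$orientation[i]
      perp <- -dx * sin(th) + dy * cos(th)
      out$perp_velocity_cm_s[i] <- perp * cfg$frame_rate_hz / cfg$px_per_cm
    }
  }
  out
}

#' Relative footprint pressure over a stance
#'
#' Per-frame footprint area, summed pixel intensity, and intensity per
#' pixel (a relative pressure readout — fTIR brightness is proportional
#' to applied pressure, without absolute calibration). Gap-filled frames
#' inside the event have no measured pixels and yield `NA`.
#'
#' @param event One-row event tibble.
#' @param cfg A [gait_config()] list (`px_per_cm`).
#' @return Tibble `frame`, `area_cm2`, `intensity`, `pressure`
#'   (intensity / area in pixels).
#' @export
pressure_series <- function(event, cfg) {
  fr <- event$frames[[1]]
  if (!length(fr)) stop("empty stance event", call. = FALSE)
  areas <- event$areas[[1]]
  bright <- event$brightness[[1]]
  tibble::tibble(
    frame = fr,
    area_cm2 = areas / cfg$px_per_cm^2,
    intensity = bright,
    pressure = ifelse(!is.na(areas) & areas > 0, bright / areas, NA_real_)
  )
}

#' Body linearity index
#'
#' The average-deviation-from-smoothed-path statistic of the stance
#' linearity index applied to the body-centre trajectory, reported in
#' millimetres.
#'
#' @param poses Per-frame pose tibble.
#' @param cfg A [gait_config()] list.
#' @param smooth_win Moving-average window in frames.
#' @return Index in mm, `NA` when fewer than `smooth_win` tracked frames.
#' @export
body_linearity_index <- function(poses, cfg, smooth_win = 15) {
  tr <- poses[poses$tracked, , drop = FALSE]
  n <- nrow(tr)
  if (n < smooth_win) return(NA_real_)
  sx <- moving_average(tr$center_x, smooth_win)
  sy <- moving_average(tr$center_y, smooth_win)
  mean(sqrt((tr$center_x - sx)^2 + (tr$center_y - sy)^2)) * 10 / cfg$px_per_cm
}
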