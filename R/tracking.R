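#' Link per-frame footprint blobs into stance events
#'
#' Greedy nearest-centroid linking in frame order: each blob extends the
#' nearest open track whose last centroid lies within `max_link_dist_px`
#' and within the per-frame stance-drift bound `max_stance_drift_px`
#' (stance prints anchor to the floor, so a true continuation is nearly
#' stationary; without the drift bound a paw landing beside a lifting
#' print would be fused into its track). When two blobs compete for one
#' track the closer one wins and the other starts a new track. A track
#' survives up to `max_gap_frames` consecutive missing frames. Gap
#' frames are filled by linear interpolation of the centroid and counted
#' as contact (area and brightness stay `NA` there). Tracks shorter than
#' `min_stance_frames` frames are discarded.
#'
#' @param blobs Tibble of per-frame blobs (from [extract_footprints()],
#'   rows in ascending frame order).
#' @param cfg A [gait_config()] list.
#' @return Nested tibble of unlabelled stance events: `event_id`, `onset`,
#'   `offset`, `mean_x`, `mean_y`, `peak_brightness`, and list-columns
#'   `frames`, `xs`, `ys`, `areas`, `brightness` covering every frame of
#'   the event.
#' @export
link_blobs <- function(blobs, cfg) {
  validate_gait_config(cfg)
  tracks <- list()       # closed
  open <- list()         # open tracks: list(frames, xs, ys, areas, bright)
  if (nrow(blobs)) {
    if (is.unsorted(blobs$frame)) stop("blobs must be in ascending frame order",
                                       call. = FALSE)
    for (f in unique(blobs$frame)) {
      fb <- blobs[blobs$frame == f, , drop = FALSE]
      # close tracks that fell out of the gap window
      if (length(open)) {
        last_f <- vapply(open, function(t) t$frames[length(t$frames)], numeric(1))
        expired <- which(f - last_f - 1 > cfg$max_gap_frames)
        tracks <- c(tracks, open[expired])
        if (length(expired)) open <- open[-expired]
      }
      nb <- nrow(fb)
      assigned_track <- rep(NA_integer_, nb)
      if (length(open) && nb) {
        lx <- vapply(open, function(t) t$xs[length(t$xs)], numeric(1))
        ly <- vapply(open, function(t) t$ys[length(t$ys)], numeric(1))
        lf <- vapply(open, function(t) t$frames[length(t$frames)], numeric(1))
        D <- outer(fb$x, lx, "-")^2 + outer(fb$y, ly, "-")^2
        # a continuation must respect the stance-drift invariant (prints
        # anchor to the floor), on top of the link radius; otherwise a paw
        # landing beside a lifting print would be fused into its track
        lim <- rep(pmin(cfg$max_link_dist_px, cfg$max_stance_drift_px),
                   length(open))
        D[sweep(sqrt(D), 2, lim, ">")] <- Inf
        ord <- order(D)
        used_t <- rep(FALSE, length(open))
        for (k in ord) {
          if (!is.finite(D[k])) break
          bi <- (k - 1) %% nb + 1
          ti <- (k - 1) %/% nb + 1
          if (is.na(assigned_track[bi]) && !used_t[ti]) {
            assigned_track[bi] <- ti
            used_t[ti] <- TRUE
          }
        }
      }
      for (bi in seq_len(nb)) {
        ti <- assigned_track[bi]
        if (is.na(ti)) {
          open[[length(open) + 1L]] <- list(
            frames = fb$frame[bi], xs = fb$x[bi], ys = fb$y[bi],
            areas = fb$area_px[bi], bright = fb$brightness_sum[bi])
        } else {
          t <- open[[ti]]
          t$frames <- c(t$frames, fb$frame[bi])
          t$xs <- c(t$xs, fb$x[bi]); t$ys <- c(t$ys, fb$y[bi])
          t$areas <- c(t$areas, fb$area_px[bi])
          t$bright <- c(t$bright, fb$brightness_sum[bi])
          open[[ti]] <- t
        }
      }
    }
  }
  tracks <- c(tracks, open)
  events <- purrr::map(tracks, fill_track_gaps)
  keep <- vapply(events, function(e) length(e$frames) >= cfg$min_stance_frames,
                 logical(1))
  events <- events[keep]
  if (!length(events)) return(empty_events())
  out <- tibble::tibble(
    event_id = seq_along(events),
    leg = NA_character_,
    ambiguous_leg = FALSE,
    onset = vapply(events, function(e) e$frames[1], numeric(1)),
    offset = vapply(events, function(e) e$frames[length(e$frames)], numeric(1)),
    mean_x = vapply(events, function(e) mean(e$xs), numeric(1)),
    mean_y = vapply(events, function(e) mean(e$ys), numeric(1)),
    peak_brightness = vapply(events, function(e) max(e$bright, na.rm = TRUE), numeric(1)),
    frames = purrr::map(events, "frames"),
    xs = purrr::map(events, "xs"),
    ys = purrr::map(events, "ys"),
    areas = purrr::map(events, "areas"),
    brightness = purrr::map(events, "bright")
  )
  dplyr::arrange(out, .data$onset, .data$mean_x)
}

empty_events <- function() {
  tibble::tibble(event_id = integer(), leg = character(),
                 ambiguous_leg = logical(),
                 onset = numeric(), offset = numeric(),
                 mean_x = numeric(), mean_y = numeric(),
                 peak_brightness = numeric(),
                 frames = list(), xs = list(), ys = list(),
                 areas = list(), brightness = list())
}

# expand a track to its full frame span; interpolate centroids across gaps
fill_track_gaps <- function(t) {
  full <- seq(t$frames[1], t$frames[length(t$frames)])
  if (length(full) == length(t$frames)) return(t)
  xs <- stats::approx(t$frames, t$xs, xout = full)$y
  ys <- stats::approx(t$frames, t$ys, xout = full)$y
  areas <- rep(NA_real_, length(full))
  bright <- rep(NA_real_, length(full))
  hit <- match(t$frames, full)
  areas[hit] <- t$areas
  bright[hit] <- t$bright
  list(frames = full, xs = xs, ys = ys, areas = areas, bright = bright)
}

#' Assign a leg identity to each stance event
#'
#' The event's mean centroid is transformed into the body frame at the
#' onset frame (nearest tracked frame if the onset pose is missing). The
#' lateral sign gives the side (positive = animal's left in the
#' bottom-view convention); the longitudinal coordinate relative to
#' `fore_hind_split` gives fore versus hind. Events landing inside the
#' `fore_hind_dead_zone` band are resolved by continuity with the most
#' recent previous event of the two candidate legs, and flagged ambiguous
#' when no such event exists.
#'
#' @param events Event tibble from [link_blobs()].
#' @param poses Per-frame pose tibble (rows from [decompose_body()]).
#' @param cfg A [gait_config()] list.
#' @return `events` with `leg` filled in (`"LF"`, `"LH"`, `"RF"`, `"RH"`)
#'   and `ambiguous_leg` set where the dead-zone fallback failed.
#' @export
assign_leg_identity <- function(events, poses, cfg) {
  if (!nrow(events)) return(events)
  tracked <- poses[poses$tracked, , drop = FALSE]
  if (!nrow(tracked)) stop("no tracked poses available", call. = FALSE)
  events <- dplyr::arrange(events, .data$onset, .data$mean_x)
  for (i in seq_len(nrow(events))) {
    pf <- tracked[which.min(abs(tracked$frame - events$onset[i])), , drop = FALSE]
    bf <- to_body_frame(events$mean_x[i], events$mean_y[i], pf)
    side <- if (bf$lateral >= 0) "L" else "R"
    dlong <- bf$longitudinal - cfg$fore_hind_split
    if (abs(dlong) > cfg$fore_hind_dead_zone) {
      events$leg[i] <- paste0(side, if (dlong >= 0) "F" else "H")
    } else {
      cands <- paste0(side, c("F", "H"))
      prevs <- events[seq_len(i - 1), , drop = FALSE]
      prevs <- prevs[!is.na(prevs$leg) & prevs$leg %in% cands, , drop = FALSE]
      if (nrow(prevs)) {
        last_per_leg <- prevs |>
          dplyr::group_by(.data$leg) |>
          dplyr::slice_max(.data$onset, n = 1, with_ties = FALSE) |>
          dplyr::ungroup()
        d <- sqrt((last_per_leg$mean_x - events$mean_x[i])^2 +
                    (last_per_leg$mean_y - events$mean_y[i])^2)
        events$leg[i] <- last_per_leg$leg[which.min(d)]
      } else {
        events$leg[i] <- paste0(side, if (dlong >= 0) "F" else "H")
        events$ambiguous_leg[i] <- TRUE
      }
    }
  }
  events
}

#' Assemble step cycles from labelled stance events
#'
#' One cycle per consecutive same-leg event pair, spanning stance onset to
#' the next stance onset: stance time from the first event, swing time the
#' gap up to the next onset, period their sum (exact in frame counts), and
#' step length the distance between the two events' mean centroids. The
#' last event of each leg opens no cycle.
#'
#' @param events Labelled event tibble from [assign_leg_identity()].
#' @param cfg A [gait_config()] list (`px_per_cm`, `frame_rate_hz`).
#' @return Tibble with one row per cycle: `leg`, `stance_onset`,
#'   `stance_offset`, `next_onset`, `stance_time`, `swing_time`, `period`
#'   (seconds), `step_length_mm`, `duty_factor`, `degenerate` (no swing
#'   detected).
#' @export
build_step_cycles <- function(events, cfg) {
  fps <- cfg$frame_rate_hz
  empty <- tibble::tibble(leg = character(), stance_onset = numeric(),
                          stance_offset = numeric(), next_onset = numeric(),
                          stance_time = numeric(), swing_time = numeric(),
                          period = numeric(), step_length_mm = numeric(),
                          duty_factor = numeric(), degenerate = logical())
  if (!nrow(events)) return(empty)
  ev <- dplyr::arrange(events[!is.na(events$leg), , drop = FALSE],
                       .data$leg, .data$onset)
  out <- list()
  for (leg in unique(ev$leg)) {
    e <- ev[ev$leg == leg, , drop = FALSE]
    if (nrow(e) >= 2 && any(e$onset[-1] <= e$offset[-nrow(e)])) {
      stop("overlapping stance events for leg ", leg, call. = FALSE)
    }
    if (nrow(e) < 2) next
    i <- seq_len(nrow(e) - 1)
    stance <- (e$offset[i] - e$onset[i] + 1) / fps
    swing <- (e$onset[i + 1] - e$offset[i] - 1) / fps
    step <- sqrt((e$mean_x[i + 1] - e$mean_x[i])^2 +
                   (e$mean_y[i + 1] - e$mean_y[i])^2) * 10 / cfg$px_per_cm
    out[[leg]] <- tibble::tibble(
      leg = leg,
      stance_onset = e$onset[i], stance_offset = e$offset[i],
      next_onset = e$onset[i + 1],
      stance_time = stance, swing_time = swing, period = stance + swing,
      step_length_mm = step,
      duty_factor = stance / (stance + swing),
      degenerate = swing <= 0
    )
  }
  if (!length(out)) return(empty)
  dplyr::arrange(dplyr::bind_rows(out), .data$stance_onset, .data$leg)
}
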